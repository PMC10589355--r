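# Shared end-to-end scenario: one target, three library ligands with
# hand-computable scores (LA/LC share the control pose, LB sits far away).

make_pipeline_inputs <- function(dir, seed = 17) {
  fx <- make_pocket_fixture(seed, planted = c(hbond = 2, pi_pi_stacked = 1,
                                              alkyl = 1), decoys = 2)
  rec_path <- file.path(dir, "receptor.pdb")
  write_pdb(fx$receptor, rec_path)
  ctrl <- fx$pose; ctrl$ligand_id <- "CTRL"
  ctrl_path <- file.path(dir, "control.sdf")
  write_poses_sdf(ctrl, ctrl_path)
  la <- fx$pose; la$ligand_id <- "LA"
  lb <- transform_coords(fx$pose, translation = c(200, 0, 0))
  lb$ligand_id <- "LB"
  lc <- fx$pose; lc$ligand_id <- "LC"
  poses_path <- file.path(dir, "poses.sdf")
  write_poses_sdf(list(la, lb, lc), poses_path)
  writeLines(c("ligand_id,target_id,binding_energy",
               "LA,T1,-10", "LB,T1,-12", "LC,T1,-10"),
             file.path(dir, "energies.csv"))
  writeLines(c("ligand_id,mw,logp,hbd,hba,tpsa",
               "LA,350,3,2,6,80", "LB,150,1,0,2,30", "LC,350,3,2,6,80"),
             file.path(dir, "properties.csv"))
  writeLines(c("ligand_id,mutagenicity,teratogenicity,tumorigenicity,irritability",
               "LA,low,low,low,low", "LB,high,high,high,high",
               "LC,low,low,low,low"), file.path(dir, "risk.csv"))
  writeLines(c("ligand_id,predisposition", "LA,low", "LB,high", "LC,low"),
             file.path(dir, "metabolism.csv"))
  list(
    targets = list(list(id = "T1", receptor = rec_path,
                        control_pose = ctrl_path, poses = poses_path)),
    energies = file.path(dir, "energies.csv"),
    properties = file.path(dir, "properties.csv"),
    risk = file.path(dir, "risk.csv"),
    metabolism = file.path(dir, "metabolism.csv"),
    seed = seed
  )
}
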
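`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the screening pipeline end to end
#'
#' Orchestrates fingerprinting, binding-mode similarity against each
#' target's control ligand, point-based scoring and ranking, and writes a
#' reproducible report bundle. Re-running the same configuration on the
#' same inputs produces byte-identical CSV output.
#'
#' The configuration (a list, or a path to a YAML/JSON file with the same
#' shape) holds:
#' \itemize{
#'   \item \code{targets}: list of \code{list(id, receptor, control_pose,
#'     poses)} — paths to the receptor PDB, the control ligand's docked
#'     pose, and the library poses (SDF, one block per ligand).
#'   \item \code{energies, properties, risk, metabolism}: CSV paths (see
#'     [read_energy_table()], [read_risk_table()]).
#'   \item \code{geometry}: named overrides for [geometry_params()].
#'   \item \code{scoring}: \code{similarity_method}
#'     (\code{"control_fraction"}/\code{"count_ratio"}) and
#'     \code{normalize} flag for [composite_score()].
#'   \item \code{output_dir}, \code{seed}.
#' }
#' Ligands present in the poses but absent from an annotation table are
#' scored with the affected component at its worst value and flagged in the
#' \code{missing_data} column (the ranking stays total).
#'
#' @param config List or path to a YAML/JSON configuration file.
#' @return Invisibly, a list with \code{scores} (ranked data.frame),
#'   \code{fingerprints} (per target), \code{files} (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                                 simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config$targets) || length(config$targets) < 1L)
    stop("configuration must define at least one target")
  for (f in c("energies", "properties", "risk", "metabolism"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("missing input table: ", f)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(geometry_params, as.list(config$geometry %||% list()))
  sim_method <- config$scoring$similarity_method %||% "control_fraction"
  normalize <- isTRUE(config$scoring$normalize)

  energies <- read_energy_table(config$energies)
  properties <- utils::read.csv(config$properties, stringsAsFactors = FALSE)
  risk <- read_risk_table(config$risk)
  metabolism <- read_metabolism_table(config$metabolism)

  targets <- vapply(config$targets, function(t) t$id, "")
  fingerprints <- list()
  sims <- list()
  ligand_ids <- character()
  files <- character()
  for (tg in config$targets) {
    for (f in c("receptor", "control_pose", "poses"))
      if (is.null(tg[[f]]) || !file.exists(tg[[f]]))
        stop("target '", tg$id, "': missing ", f, " file")
    receptor <- read_receptor(tg$receptor)
    control <- read_poses(tg$control_pose)[[1]]
    cfp <- fingerprint(control, receptor, params, target_id = tg$id)
    if (!length(cfp$residues))
      stop("control fingerprint for target '", tg$id,
           "' is empty; cannot compute binding-mode similarity")
    poses <- read_poses(tg$poses, energies, tg$id)
    fps <- lapply(poses, fingerprint, receptor = receptor, params = params,
                  target_id = tg$id)
    names(fps) <- vapply(poses, `[[`, "", "ligand_id")
    fingerprints[[tg$id]] <- fps
    ligand_ids <- union(ligand_ids, names(fps))
    sims[[tg$id]] <- data.frame(
      ligand_id = names(fps), target_id = tg$id,
      sim_bm = vapply(fps, similarity_bm, numeric(1), control = cfp,
                      method = sim_method),
      stringsAsFactors = FALSE)
    fp_path <- file.path(out_dir, paste0("fingerprints_", tg$id, ".json"))
    writeLines(jsonlite::toJSON(lapply(fps, function(fp) list(
      ligand_id = fp$ligand_id, target_id = fp$target_id,
      residues = fp$residues)), auto_unbox = TRUE, pretty = TRUE), fp_path)
    files <- c(files, fp_path)
  }
  similarities <- do.call(rbind, sims)
  scores <- score_library(ligand_ids, targets, energies, similarities,
                          properties, risk, metabolism, normalize = normalize)
  ranked <- rank_library(scores)
  for (col in c("abs_be", "sim_bm", "composite"))
    ranked[[col]] <- round(ranked[[col]], 4)
  score_path <- file.path(out_dir, "scores.csv")
  utils::write.csv(ranked, score_path, row.names = FALSE)
  manifest <- list(package = "dualscreen",
                   version = as.character(utils::packageVersion("dualscreen")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed %||% NA,
                   similarity_method = sim_method, normalize = normalize,
                   geometry = unclass(params), config = config)
  man_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"), man_path)
  invisible(list(scores = ranked, fingerprints = fingerprints,
                 files = c(files, score_path, man_path)))
}

#' Two-dimensional contact summary of a fingerprint
#'
#' Condenses a fingerprint into one row per interacting residue — the
#' tabular equivalent of a 2D ligand-interaction map: which residues are
#' contacted, through which interaction types, and how closely.
#'
#' @param fp A [fingerprint()].
#' @return data.frame with columns \code{residue, chain, resno, types}
#'   (comma-separated, generic contacts listed last), \code{min_distance}
#'   and \code{n_records}, sorted by residue number.
#' @export
report_contacts <- function(fp) {
  stopifnot(inherits(fp, "ContactFingerprint"))
  rec <- fp$records
  if (!nrow(rec))
    return(data.frame(residue = character(), chain = character(),
                      resno = integer(), types = character(),
                      min_distance = numeric(), n_records = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(rec, rec$reskey), function(r) {
    ty <- unique(r$type)
    ty <- c(sort(setdiff(ty, "generic_contact")),
            intersect("generic_contact", ty))
    data.frame(residue = r$residue[1], chain = r$chain[1], resno = r$resno[1],
               types = paste(ty, collapse = ","),
               min_distance = min(r$distance), n_records = nrow(r),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}
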
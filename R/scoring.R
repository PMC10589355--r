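# The point-based virtual-screening score: binding-mode similarity against a
# control ligand, drug-likeness range points, toxicity-risk points, a
# toxic-metabolism penalty, and their summative composite.

fp_residues <- function(x) {
  if (inherits(x, "ContactFingerprint")) x$residues else as.character(x)
}

#' Binding-mode similarity against a control ligand (percent)
#'
#' The binding-mode similarity of a tested ligand is the percentage of the
#' control ligand's interacting residues that the tested ligand also
#' contacts: \code{100 * |test n control| / |control|} (a rule of three with
#' the control set corresponding to 100). The alternative literal count
#' ratio \code{100 * |test| / |control|} is available as
#' \code{method = "count_ratio"} for comparison only — it rewards
#' promiscuous binders and can exceed 100, so it is not the default.
#'
#' @param test,control [fingerprint()] objects or character vectors of
#'   residue keys; the control is the reference ligand with demonstrated
#'   affinity (e.g. G1-PABA on GPER, Gossypol on Bcl-2).
#' @param method \code{"control_fraction"} (default) or \code{"count_ratio"}.
#' @return Similarity in percent.
#' @examples
#' similarity_bm(c("A:1:PHE", "A:2:LEU"), c("A:1:PHE", "A:3:SER"))  # 50
#' @export
similarity_bm <- function(test, control,
                          method = c("control_fraction", "count_ratio")) {
  method <- match.arg(method)
  test <- unique(fp_residues(test))
  control <- unique(fp_residues(control))
  if (!length(control))
    stop("control fingerprint has no interacting residues; similarity undefined")
  if (method == "control_fraction")
    100 * length(intersect(test, control)) / length(control)
  else
    100 * length(test) / length(control)
}

#' Drug-likeness range points
#'
#' Awards 10 points for each physicochemical parameter inside its screening
#' range (boundaries inclusive): molecular weight 200-500 g/mol, log P 2-5,
#' hydrogen-bond acceptors 5-10, hydrogen-bond donors 2-5. Note the acceptor
#' and donor ranges penalize low counts as well as high ones — they are
#' screening windows, not the classical one-sided rule-of-five limits.
#'
#' @param props One-row data.frame with columns \code{mw, logp, hba, hbd}
#'   (e.g. from [compute_properties()]), or NULL when the individual values
#'   are given.
#' @param mw,logp,hba,hbd Individual values, used when \code{props} is NULL.
#' @return Integer points in \{0, 10, 20, 30, 40\}.
#' @examples
#' lipinski_points(mw = 350, logp = 3, hba = 6, hbd = 2)   # 40
#' @export
lipinski_points <- function(props = NULL, mw = props$mw, logp = props$logp,
                            hba = props$hba, hbd = props$hbd) {
  vals <- c(mw = mw, logp = logp, hba = hba, hbd = hbd)
  if (length(vals) != 4L || anyNA(vals))
    stop("lipinski_points needs mw, logp, hba and hbd")
  in_range <- c(mw >= 200 & mw <= 500,
                logp >= 2 & logp <= 5,
                hba >= 5 & hba <= 10,
                hbd >= 2 & hbd <= 5)
  10L * sum(in_range)
}

.risk_endpoints <- c("mutagenicity", "teratogenicity", "tumorigenicity",
                     "irritability")
.risk_points <- c(high = 0L, medium = 10L, low = 20L)

#' Toxicity-risk points
#'
#' Sums, over the four predicted endpoints (mutagenicity, teratogenicity,
#' tumorigenicity, irritability), 0 points for a high-risk call, 10 for
#' medium and 20 for low.
#'
#' @param risk Named character vector or one-row data.frame giving a level
#'   (\code{"high"}, \code{"medium"} or \code{"low"}) for each of the four
#'   endpoints.
#' @return Integer points in \{0, 10, ..., 80\}.
#' @examples
#' tox_points(c(mutagenicity = "low", teratogenicity = "low",
#'              tumorigenicity = "medium", irritability = "high"))  # 50
#' @export
tox_points <- function(risk) {
  if (is.data.frame(risk)) risk <- unlist(risk[1, , drop = TRUE])
  risk <- unlist(risk)
  missing <- setdiff(.risk_endpoints, names(risk))
  if (length(missing))
    stop("missing toxicity endpoint(s): ", paste(missing, collapse = ", "))
  lv <- as.character(risk[.risk_endpoints])
  if (!all(lv %in% names(.risk_points)))
    stop("risk levels must be high/medium/low, got: ",
         paste(setdiff(lv, names(.risk_points)), collapse = ", "))
  sum(.risk_points[lv])
}

#' Toxic-metabolism penalty
#'
#' Penalty for predicted predisposition to toxic-metabolite formation in
#' first-pass (CYP450) metabolism, restricted by convention to the variable
#' moiety added in the amide-coupling step: high subtracts 20 points, medium
#' 15 and low 10.
#'
#' @param level \code{"high"}, \code{"medium"} or \code{"low"}.
#' @return Negative integer: -20, -15 or -10.
#' @export
metabolism_penalty <- function(level) {
  pts <- c(high = -20L, medium = -15L, low = -10L)
  level <- as.character(level)
  if (length(level) != 1L || !(level %in% names(pts)))
    stop("metabolism level must be one of high/medium/low")
  pts[[level]]
}

#' Summative composite score
#'
#' The final screening score is the sum over targets of the docking-energy
#' magnitude |BE| (kcal/mol) and the binding-mode similarity (percent), plus
#' the ligand-level drug-likeness points, toxicity points and metabolism
#' penalty counted once. The terms are summed unscaled, mixing units by
#' construction; higher is better. \code{normalize = TRUE} optionally
#' rescales each per-target |BE| by dividing by the maximum |BE| in the
#' library and multiplying by 100, putting it on the similarity scale (off
#' by default; the unscaled sum is the protocol's definition).
#'
#' @param per_target data.frame with one row per target and columns
#'   \code{abs_be} (>= 0) and \code{sim_bm} (0-100).
#' @param lipinski,tox,metabolism Ligand-level point terms (see
#'   [lipinski_points()], [tox_points()], [metabolism_penalty()]).
#' @param normalize Logical; see above.
#' @param be_scale Maximum |BE| used when \code{normalize = TRUE}.
#' @return Composite score (numeric).
#' @examples
#' composite_score(data.frame(abs_be = 8, sim_bm = 50), 30, 60, -15)  # 133
#' @export
composite_score <- function(per_target, lipinski, tox, metabolism,
                            normalize = FALSE, be_scale = NULL) {
  stopifnot(nrow(per_target) >= 1L,
            all(c("abs_be", "sim_bm") %in% names(per_target)))
  if (any(per_target$abs_be < 0))
    stop("abs_be must be a magnitude (>= 0)")
  if (any(per_target$sim_bm < 0 | per_target$sim_bm > 100))
    stop("sim_bm must lie in [0, 100]")
  be <- per_target$abs_be
  if (normalize) {
    if (is.null(be_scale) || be_scale <= 0)
      stop("normalize = TRUE needs a positive be_scale")
    be <- 100 * be / be_scale
  }
  sum(be + per_target$sim_bm) + lipinski + tox + metabolism
}

#' Score a ligand library
#'
#' Assembles per-ligand, per-target score components from the input tables
#' and computes the composite. Ligands missing from an annotation table are
#' scored with the affected component at its worst value (similarity 0,
#' |BE| 0, drug-likeness 0 points, all-high risk, high metabolism
#' predisposition) and flagged in \code{missing_data}, so the ranking stays
#' total.
#'
#' @param ligand_ids Character vector of ligands to score.
#' @param targets Character vector of target ids (e.g. \code{c("GPER",
#'   "BCL2")}).
#' @param energies [read_energy_table()] table (signed kcal/mol).
#' @param similarities data.frame \code{ligand_id, target_id, sim_bm}.
#' @param properties data.frame \code{ligand_id, mw, logp, hbd, hba, tpsa}.
#' @param risk data.frame \code{ligand_id} plus the four endpoint columns.
#' @param metabolism data.frame \code{ligand_id, predisposition}.
#' @param normalize,be_scale Passed to [composite_score()]; \code{be_scale}
#'   defaults to the largest |BE| in \code{energies} when normalizing.
#' @return data.frame with one row per (ligand, target):
#'   \code{ligand_id, target_id, abs_be, sim_bm, lipinski_points, tox_points,
#'   metabolism_penalty, composite, missing_data} — ready for
#'   [rank_library()].
#' @export
score_library <- function(ligand_ids, targets, energies, similarities,
                          properties, risk, metabolism, normalize = FALSE,
                          be_scale = NULL) {
  stopifnot(length(ligand_ids) >= 1L, length(targets) >= 1L)
  if (anyDuplicated(ligand_ids))
    stop("duplicate ligand ids: ",
         paste(unique(ligand_ids[duplicated(ligand_ids)]), collapse = ", "))
  if (normalize && is.null(be_scale))
    be_scale <- max(abs(energies$binding_energy), 1e-9)
  rows <- list()
  for (lig in ligand_ids) {
    missing <- character()
    pt <- data.frame(target_id = targets, abs_be = 0, sim_bm = 0)
    for (t in seq_along(targets)) {
      e <- energy_for(energies, lig, targets[t])
      if (is.na(e)) missing <- c(missing, paste0("energy:", targets[t]))
      else pt$abs_be[t] <- abs(e)
      s <- similarities$sim_bm[similarities$ligand_id == lig &
                                 similarities$target_id == targets[t]]
      if (!length(s) || is.na(s[1]))
        missing <- c(missing, paste0("sim:", targets[t]))
      else pt$sim_bm[t] <- s[1]
    }
    pr <- properties[properties$ligand_id == lig, , drop = FALSE]
    lp <- if (nrow(pr)) lipinski_points(pr[1, ]) else {
      missing <- c(missing, "properties"); 0L
    }
    rk <- risk[risk$ligand_id == lig, , drop = FALSE]
    tp <- if (nrow(rk)) tox_points(rk[1, .risk_endpoints]) else {
      missing <- c(missing, "risk"); 0L
    }
    mb <- metabolism[metabolism$ligand_id == lig, , drop = FALSE]
    mp <- if (nrow(mb)) metabolism_penalty(mb$predisposition[1]) else {
      missing <- c(missing, "metabolism"); -20L
    }
    comp <- composite_score(pt, lp, tp, mp, normalize = normalize,
                            be_scale = be_scale)
    rows[[lig]] <- data.frame(
      ligand_id = lig, target_id = pt$target_id, abs_be = pt$abs_be,
      sim_bm = pt$sim_bm, lipinski_points = lp, tox_points = tp,
      metabolism_penalty = mp, composite = comp,
      missing_data = paste(missing, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank a scored library
#'
#' Orders ligands by composite score (descending), breaking ties by ligand
#' id (ascending, lexicographic, C collation) so the ranking is fully
#' deterministic; ranks 1..N are assigned per ligand and repeated across
#' that ligand's target rows.
#'
#' @param scores Output of [score_library()] (or any data.frame with
#'   \code{ligand_id} and \code{composite}).
#' @return The input with a \code{rank} column, rows sorted by rank.
#' @export
rank_library <- function(scores) {
  if (!nrow(scores)) {
    scores$rank <- integer()
    return(scores)
  }
  per <- unique(scores[, c("ligand_id", "composite")])
  if (anyDuplicated(per$ligand_id))
    stop("conflicting composite scores for a ligand id")
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  per <- per[order(-per$composite, per$ligand_id), , drop = FALSE]
  per$rank <- seq_len(nrow(per))
  scores$rank <- per$rank[match(scores$ligand_id, per$ligand_id)]
  scores[order(scores$rank, match(scores$target_id, unique(scores$target_id))), ,
         drop = FALSE]
}

#' Read risk / metabolism annotation tables
#'
#' @param path CSV path. Risk tables need columns \code{ligand_id,
#'   mutagenicity, teratogenicity, tumorigenicity, irritability}; metabolism
#'   tables \code{ligand_id, predisposition}. Levels must be
#'   high/medium/low.
#' @return data.frame.
#' @export
read_risk_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand_id", .risk_endpoints)
  if (!all(need %in% names(tab)))
    stop("risk CSV must have columns ", paste(need, collapse = ","))
  for (ep in .risk_endpoints)
    if (!all(tab[[ep]] %in% names(.risk_points)))
      stop("invalid level(s) in column ", ep)
  tab
}

#' @rdname read_risk_table
#' @export
read_metabolism_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand_id", "predisposition") %in% names(tab)))
    stop("metabolism CSV must have columns ligand_id,predisposition")
  if (!all(tab$predisposition %in% c("high", "medium", "low")))
    stop("predisposition levels must be high/medium/low")
  tab
}
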
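# The Bcl-2 residue sets printed for the control (Gossypol) and the shared
# binding site of the two leads; used for the worked similarity example.
gossypol_bcl2 <- c("Asp111", "Phe112", "Met115", "Gln118", "Leu119", "His120",
                   "Phe130", "Ala131", "Thr132", "Val133", "Leu137", "Phe153",
                   "Met157")
leads_bcl2 <- c("Phe130", "Ala131", "Thr132", "Val133", "Leu137", "Phe153",
                "Met157")

test_that("binding-mode similarity is the shared fraction of the control set", {
  expect_equal(similarity_bm(gossypol_bcl2, gossypol_bcl2), 100)
  expect_equal(similarity_bm(c("X1", "X2"), gossypol_bcl2), 0)
  expect_equal(round(similarity_bm(leads_bcl2, gossypol_bcl2), 2), 53.85)
  expect_equal(similarity_bm(leads_bcl2, gossypol_bcl2), 100 * 7 / 13,
               tolerance = 1e-9)
  expect_error(similarity_bm(leads_bcl2, character(0)), "undefined")
  # order-free; shared residues never decrease it; unshared never change it
  set.seed(7)
  for (k in 1:20) {
    test <- sample(gossypol_bcl2, sample(0:13, 1))
    s <- similarity_bm(test, gossypol_bcl2)
    expect_equal(similarity_bm(sample(test), sample(gossypol_bcl2)), s)
    extra_shared <- setdiff(gossypol_bcl2, test)
    if (length(extra_shared))
      expect_gte(similarity_bm(c(test, extra_shared[1]), gossypol_bcl2), s)
    expect_equal(similarity_bm(c(test, "Zzz999"), gossypol_bcl2), s)
  }
  # the literal count-ratio reading stays available and can exceed 100
  expect_gt(similarity_bm(c(gossypol_bcl2, "Zzz999"), gossypol_bcl2,
                          method = "count_ratio"), 100)
})

test_that("drug-likeness points award 10 per in-range parameter, inclusive", {
  expect_equal(lipinski_points(mw = 350, logp = 3, hba = 6, hbd = 2), 40)
  expect_equal(lipinski_points(mw = 566.05, logp = 5.5, hba = 7, hbd = 1), 10)
  expect_equal(lipinski_points(mw = 150, logp = 1, hba = 2, hbd = 0), 0)
  # closed boundaries on all four ranges
  expect_equal(lipinski_points(mw = 200, logp = 2, hba = 5, hbd = 2), 40)
  expect_equal(lipinski_points(mw = 500, logp = 5, hba = 10, hbd = 5), 40)
  expect_equal(lipinski_points(mw = 199.999, logp = 5.001, hba = 4, hbd = 6), 0)
  # codomain is exactly the multiples of 10 up to 40
  set.seed(11)
  pts <- replicate(200, lipinski_points(mw = stats::runif(1, 50, 900),
                                        logp = stats::runif(1, -3, 9),
                                        hba = sample(0:15, 1),
                                        hbd = sample(0:9, 1)))
  expect_true(all(pts %in% c(0L, 10L, 20L, 30L, 40L)))
})

test_that("toxicity points cover all level combinations exhaustively", {
  lev <- c("high", "medium", "low")
  combos <- expand.grid(mutagenicity = lev, teratogenicity = lev,
                        tumorigenicity = lev, irritability = lev,
                        stringsAsFactors = FALSE)
  map <- c(high = 0L, medium = 10L, low = 20L)
  for (i in seq_len(nrow(combos))) {
    got <- tox_points(unlist(combos[i, ]))
    expect_identical(got, sum(map[unlist(combos[i, ])]))
    expect_true(got %in% seq(0L, 80L, by = 10L))
  }
  expect_equal(tox_points(c(mutagenicity = "low", teratogenicity = "low",
                            tumorigenicity = "low", irritability = "low")), 80)
  expect_error(tox_points(c(mutagenicity = "low")), "missing")
  expect_error(tox_points(c(mutagenicity = "severe", teratogenicity = "low",
                            tumorigenicity = "low", irritability = "low")),
               "high/medium/low")
})

test_that("metabolism penalties are -20/-15/-10 and nothing else", {
  expect_identical(metabolism_penalty("high"), -20L)
  expect_identical(metabolism_penalty("medium"), -15L)
  expect_identical(metabolism_penalty("low"), -10L)
  expect_error(metabolism_penalty("none"), "high/medium/low")
})

test_that("composite score is the unscaled summative total", {
  expect_equal(composite_score(data.frame(abs_be = 8, sim_bm = 50),
                               30, 60, -15), 133)
  expect_equal(composite_score(data.frame(abs_be = 0, sim_bm = 0),
                               0, 0, -10), -10)
  expect_equal(composite_score(data.frame(abs_be = c(10.93, 8.0),
                                          sim_bm = c(53.85, 50)),
                               10, 40, -15), 157.78)
  expect_error(composite_score(data.frame(abs_be = -1, sim_bm = 0), 0, 0, -10),
               "magnitude")
  # brute-force re-summation on random component tables, exact
  set.seed(13)
  for (k in 1:1000) {
    nt <- sample(1:3, 1)
    be <- stats::runif(nt, 0, 15); sim <- stats::runif(nt, 0, 100)
    lp <- sample(seq(0, 40, 10), 1); tx <- sample(seq(0, 80, 10), 1)
    mp <- sample(c(-20L, -15L, -10L), 1)
    brute <- 0
    for (t in seq_len(nt)) brute <- brute + be[t] + sim[t]
    brute <- brute + lp + tx + mp
    expect_identical(composite_score(data.frame(abs_be = be, sim_bm = sim),
                                     lp, tx, mp), brute)
  }
})

test_that("ranking is deterministic with id tie-breaks", {
  sc <- data.frame(ligand_id = c("A", "B"), target_id = "T",
                   composite = c(10, 20))
  expect_identical(rank_library(sc)$ligand_id, c("B", "A"))
  tie <- data.frame(ligand_id = c("B", "A"), target_id = "T",
                    composite = c(10, 10))
  expect_identical(rank_library(tie)$ligand_id, c("A", "B"))
  empty <- data.frame(ligand_id = character(), target_id = character(),
                      composite = numeric())
  expect_equal(nrow(rank_library(empty)), 0)
  # permutation stability: shuffled input, identical output
  set.seed(3)
  sc <- data.frame(ligand_id = sprintf("L%02d", 1:40), target_id = "T",
                   composite = sample(c(stats::runif(30, 0, 200),
                                        rep(55, 10))))
  r1 <- rank_library(sc)
  for (k in 1:5) {
    r2 <- rank_library(sc[sample(nrow(sc)), , drop = FALSE])
    expect_identical(r2$ligand_id, r1$ligand_id)
    expect_identical(r2$rank, r1$rank)
  }
  expect_identical(sort(unique(r1$rank)), 1:40)
})

test_that("library scoring flags missing annotations at worst-case values", {
  lib <- make_ligand_library(5, 4, targets = "T1")
  risk_missing <- lib$risk[-2, , drop = FALSE]
  sc <- score_library(lib$properties$ligand_id, "T1", lib$energies,
                      lib$similarities, lib$properties, risk_missing,
                      lib$metabolism)
  miss <- sc[sc$ligand_id == lib$properties$ligand_id[2], ]
  expect_identical(miss$tox_points, 0L)
  expect_match(miss$missing_data, "risk")
  expect_identical(sc$missing_data[sc$ligand_id != miss$ligand_id[1]],
                   rep("", 3))
})
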
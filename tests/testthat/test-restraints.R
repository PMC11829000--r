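test_that("structured segments are maximal confident runs", {
  expect_equal(detect_structured_segments(c(80, 80, 60, 80), 75, 2),
               cbind(start = 0L, end = 2L))
  expect_equal(nrow(detect_structured_segments(rep(50, 8), 75, 2)), 0)
  expect_equal(detect_structured_segments(rep(80, 10), 75, 2),
               cbind(start = 0L, end = 10L))
  # min_len = 1 keeps singletons
  expect_equal(nrow(detect_structured_segments(c(50, 80, 50), 75, 1)), 1)
  expect_error(detect_structured_segments(numeric(0)), "empty")
})

test_that("PAE cutoff branches on hydropathy and confident stretches", {
  hydrophilic <- strrep("E", 20)  # KD -3.5
  hydrophobic <- strrep("I", 20)  # KD +4.5
  with_stretch <- c(rep(80, 6), rep(40, 14))
  without <- c(rep(80, 4), rep(40, 16))
  expect_equal(choose_pae_cutoff(hydrophilic, with_stretch), 10)
  expect_equal(choose_pae_cutoff(hydrophilic, without), 5)
  expect_equal(choose_pae_cutoff(hydrophobic, with_stretch), 5)
  expect_error(choose_pae_cutoff(hydrophilic, rep(40, 3)), "match")
})

test_that("selection applies tail, PAE, segment and separation filters", {
  # two distant pairs differing only in tail mass around the 0.02 threshold
  p1 <- rep(0, 64); p1[30] <- 0.97; p1[64] <- 0.03
  p2 <- rep(0, 64); p2[30] <- 0.99; p2[64] <- 0.01
  probs <- rbind(p1, p2, matrix(rep(c(rep(0, 29), 1, rep(0, 34)), 4),
                                4, 64, byrow = TRUE))
  pairs <- rbind(c(0L, 1L), c(0L, 2L), c(0L, 3L), c(0L, 4L), c(1L, 3L),
                 c(2L, 4L))
  d <- distogram("GSGSG", probs, pairs = pairs)
  ann <- permissive_annotations(5)
  rs <- select_restraints(d, ann, min_separation = 1)
  kept <- paste(rs$restraints$i, rs$restraints$j)
  expect_false("0 1" %in% kept)   # tail 0.03 > 0.02
  expect_true("0 2" %in% kept)    # tail 0.01 passes
  expect_equal(unname(rs$provenance["tail"]), 1)

  # PAE filter on the symmetrized matrix
  ann2 <- permissive_annotations(5)
  ann2$pae[1, 3] <- 12;  ann2$pae[3, 1] <- 3   # max = 12 -> dropped
  ann2$pae[1, 4] <- 3;   ann2$pae[4, 1] <- 4.5 # max = 4.5 < 5 -> kept
  rs2 <- select_restraints(d, ann2, min_separation = 1)
  kept2 <- paste(rs2$restraints$i, rs2$restraints$j)
  expect_false("0 2" %in% kept2)
  expect_true("0 3" %in% kept2)   # cutoff is 5 here (no confident stretch)
  expect_equal(rs2$pae_cutoff, 5)

  # structured-segment exclusion beats perfect PAE and zero tail
  ann3 <- permissive_annotations(5)
  ann3$plddt[1:2] <- 90
  rs3 <- select_restraints(d, ann3, min_separation = 1)
  expect_equal(unname(rs3$structured_segments[1, ]), c(0L, 2L))
  expect_false(any(rs3$restraints$i %in% 0:1 | rs3$restraints$j %in% 0:1))

  # separation filter
  rs4 <- select_restraints(d, ann, min_separation = 3)
  expect_true(all(rs4$restraints$j - rs4$restraints$i >= 3))
})

test_that("filters are monotone in their thresholds", {
  d <- random_distogram(8, seed = 4)
  set.seed(9)
  ann <- list(plddt = runif(8, 20, 70),
              pae = matrix(runif(64, 0, 12), 8, 8))
  kept_set <- function(tail, minsep) {
    rs <- suppressWarnings(select_restraints(d, ann, tail_threshold = tail,
                                             min_separation = minsep))
    paste(rs$restraints$i, rs$restraints$j)
  }
  loose <- kept_set(0.9, 1)
  tight <- kept_set(0.02, 3)
  expect_true(all(tight %in% loose))
})

test_that("fully confident chain yields segments everywhere and no restraints", {
  d <- random_distogram(6, seed = 2)
  ann <- list(plddt = rep(100, 6), pae = matrix(0.5, 6, 6))
  expect_warning(rs <- select_restraints(d, ann), "empty")
  expect_equal(unname(rs$structured_segments[1, ]), c(0L, 6L))
  expect_equal(nrow(rs$restraints), 0)
})

test_that("annotation readers parse the exchange formats", {
  pae <- matrix(runif(16, 0, 20), 4, 4)
  pp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(predicted_aligned_error = pae), pp, digits = NA)
  expect_equal(read_pae(pp), pae, tolerance = 1e-12, ignore_attr = TRUE)
  tp <- tempfile(fileext = ".tsv")
  write.table(data.frame(1:4, c(80.5, 40, 60, 99)), tp, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  expect_equal(read_plddt(tp), c(80.5, 40, 60, 99))
  # 0-1 scale is rescaled
  write.table(data.frame(1:4, c(0.8, 0.4, 0.6, 0.99)), tp, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  expect_equal(read_plddt(tp), c(80, 40, 60, 99))
  unlink(c(pp, tp))
})

test_that("restraint sets serialize to TSV with a JSON sidecar", {
  d <- random_distogram(6, seed = 5)
  rs <- suppressWarnings(select_restraints(d, permissive_annotations(6)))
  path <- tempfile(fileext = ".tsv")
  write_restraints(rs, path)
  tb <- read.table(path, header = TRUE)
  expect_equal(nrow(tb), nrow(rs$restraints))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$pae_cutoff, rs$pae_cutoff)
  unlink(c(path, paste0(path, ".json")))
})
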
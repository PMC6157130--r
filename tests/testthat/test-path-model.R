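# model construction, path enumeration, parameter counting

test_that("endogenous count is 8 lipid visits plus one per CpG", {
  expect_length(path_model(default_locus(1))$endogenous, 9L)
  expect_length(path_model(default_locus(4))$endogenous, 12L)
  expect_length(path_model(default_locus(0))$endogenous, 8L)
})

test_that("default 1-CpG structure has exactly 15 SNP->TG4 simple paths", {
  m <- path_model(default_locus(1))
  paths <- enumerate_paths(m, "SNP", "TG4")
  expect_length(paths, 15L)
  expect_equal(length(paths), brute_force_path_count(m, "SNP", "TG4"))
  # deterministic lexicographic order
  expect_identical(paths, enumerate_paths(m, "SNP", "TG4"))
  key <- vapply(paths, paste, "", collapse = "\r")
  expect_false(is.unsorted(key))
})

test_that("enumeration matches the adjacency-power oracle on varied models", {
  for (ncpg in 0:3) {
    m <- path_model(default_locus(ncpg))
    for (sink in c("TG4", "TG3", "HDL4"))
      expect_equal(length(enumerate_paths(m, "SNP", sink)),
                   brute_force_path_count(m, "SNP", sink))
  }
  for (seed in 1:5) {
    sys <- random_system(seed)
    m <- sys$model
    expect_equal(length(enumerate_paths(m, m$exogenous[1],
                                        m$endogenous[length(m$endogenous)])),
                 brute_force_path_count(m, m$exogenous[1],
                                        m$endogenous[length(m$endogenous)]))
  }
})

test_that("reported five-step chains are all enumerated verbatim", {
  m <- path_model(default_locus(0))
  rendered <- vapply(enumerate_paths(m, "SNP", "TG4"), format_chain, "")
  arrow <- " → "
  chains <- c(
    paste(c("SNP", "TG1", "TG2", "TG3", "TG4"), collapse = arrow),
    paste(c("SNP", "HDL1", "HDL2", "TG2", "TG3", "TG4"), collapse = arrow),
    paste(c("SNP", "HDL1", "HDL2", "HDL3", "TG3", "TG4"), collapse = arrow),
    paste(c("SNP", "HDL1", "HDL2", "HDL3", "HDL4", "TG4"), collapse = arrow),
    paste(c("SNP", "HDL1", "TG1", "TG2", "TG3", "TG4"), collapse = arrow),
    paste(c("SNP", "HDL3", "HDL4", "TG4"), collapse = arrow),
    paste(c("SNP", "HDL3", "TG3", "TG4"), collapse = arrow),
    paste(c("SNP", "HDL1", "TG1", "TG2", "TG3", "TG4"), collapse = arrow))
  expect_true(all(chains %in% rendered))
  # the methylation-mediated chain at a locus with CpGs
  m2 <- path_model(locus_config("rs4765127", "12", 123026120L, eaf = 0.672,
                                cpg_ids = c("cg19078769", "cg00201185",
                                            "cg10922530", "cg02647265")))
  rendered2 <- vapply(enumerate_paths(m2, "SNP", "TG4"), format_chain, "")
  expect_true(paste(c("SNP", "cg02647265", "TG2", "TG3", "TG4"),
                    collapse = arrow) %in% rendered2)
})

test_that("overrides edit the structure and cycles are rejected", {
  snp_edges <- data.frame(from = "SNP",
                          to = c(paste0("TG", 1:4), paste0("HDL", 1:4), "cg01"))
  m <- path_model(default_locus(1), overrides = list(remove = snp_edges))
  expect_length(enumerate_paths(m, "SNP", "TG4"), 0L)
  expect_error(
    path_model(default_locus(1),
               overrides = list(add = data.frame(from = "TG4", to = "TG1"))),
    "cyclic")
  expect_error(enumerate_paths(m, "SNP", "nope"), "unknown")
})

test_that("free-parameter count follows the edge + 2p convention", {
  m0 <- new_path_model(c("A", "B"), "X", data.frame(from = "X", to = "A"))
  m00 <- new_path_model(c("A", "B"), "X",
                        data.frame(from = character(0), to = character(0)))
  expect_equal(count_free_parameters(m00), 4L)  # intercept + variance each
  expect_equal(count_free_parameters(m0), 5L)
  # each CpG adds exactly 4: SNP->CpG, CpG->TG2, intercept, variance
  counts <- vapply(0:4, function(k)
    count_free_parameters(path_model(default_locus(max(k, 0)))), 0L)
  expect_equal(diff(counts), rep(4L, 4))
  # removing one edge decreases the count by exactly 1
  m <- path_model(default_locus(1))
  m2 <- path_model(default_locus(1),
                   overrides = list(remove = data.frame(from = "HDL4",
                                                        to = "TG4")))
  expect_equal(count_free_parameters(m) - count_free_parameters(m2), 1L)
})

test_that("model serialization writes a readable structure file", {
  m <- path_model(default_locus(1))
  p <- tempfile(fileext = ".txt")
  write_path_model(m, p)
  txt <- readLines(p)
  expect_true(any(grepl("^free_parameters: ", txt)))
  expect_true(any(grepl("SNP -> TG4", txt)))
})
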
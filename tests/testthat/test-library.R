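test_that("profiles count identities and frequencies exactly", {
  seqs <- rbind(c("A", "G"), c("A", "G"), c("S", "G"), c("S", "Q"))
  colnames(seqs) <- c("10", "20")
  prof <- compile_profile(seqs, wild_type = c(`10` = "A", `20` = "G"))
  expect_equal(prof$positions[["10"]]$freq, c(A = 0.5, S = 0.5))
  expect_equal(prof$positions[["20"]]$counts, c(G = 3L, Q = 1L))
  # one model: every position at frequency 1
  one <- compile_profile(seqs[1, , drop = FALSE])
  expect_true(all(unlist(lapply(one$positions, function(p) p$freq)) == 1))
  # planted multinomial over 49 models reproduces its own counts
  tp <- make_toy_profile("table1")
  expect_equal(tp$profile$n_models, 49)
  expect_equal(sum(tp$profile$positions[["32"]]$counts), 49)
  expect_true(all(abs(unlist(lapply(tp$profile$positions, function(p)
    sum(p$freq))) - 1) < 1e-12))
  expect_error(compile_profile(matrix(c("A", NA), 1)), "named|completeness")
})

test_that("exact diversity arithmetic agrees with an independent big-integer oracle", {
  tab <- onby_library_table()
  expect_identical(as.character(tab$spec$diversity), "159252480")
  sizes <- vapply(tab$spec$positions, function(p) length(p$allowed),
                  integer(1))
  expect_identical(as.character(exact_product(sizes)),
                   oracle_bigproduct(sizes))
  # random specs, including results far beyond 10^40
  set.seed(8)
  for (i in 1:10) {
    sz <- sample(1:20, sample(20:40, 1), replace = TRUE)
    expect_identical(as.character(exact_product(sz)), oracle_bigproduct(sz))
  }
  expect_identical(as.character(theoretical_diversity(30)),
                   oracle_bigproduct(rep(20, 30)))
  expect_identical(as.character(theoretical_diversity(0)), "1")
  # singleton sets multiply to one
  spec1 <- library_spec(list(`1` = "A", `2` = "G"))
  expect_identical(as.character(spec1$diversity), "1")
})

test_that("published design-space sizes render at the printed precision", {
  expect_identical(format_sci(theoretical_diversity(26)), "6.7e+33")
  expect_equal(round(exact_log10(theoretical_diversity(30))), 39)
  expect_identical(format_sci(onby_library_table()$spec$diversity),
                   "1.6e+08")
})

test_that("curation applies its four rules in order and logs every action", {
  seqs <- do.call(cbind, list(
    `5` = c(rep("A", 45), rep("G", 3), rep("W", 2)),   # W below 5%
    `6` = c(rep("S", 25), rep("T", 25)),               # S/T collapse
    `7` = c(rep("L", 46), rep("I", 4)),                # distal conservative
    `8` = c(rep("A", 30), rep("Q", 20))))              # wt reinstatement
  seqs <- seqs[1:50, ]
  colnames(seqs) <- as.character(5:8)
  wt <- c(`5` = "A", `6` = "S", `7` = "L", `8` = "Y")
  prof <- compile_profile(seqs, wild_type = wt)
  rules <- curation_rules(min_frequency = 0.05,
                          distal_conservative_removals = list(`7` = "I"),
                          wt_reinstatement_positions = "8")
  spec <- curate_profile(prof, rules)
  expect_equal(spec$positions[["5"]]$allowed, c("A", "G"))
  # at 6 the S/T collapse leaves wild type alone, so the position drops
  expect_false("6" %in% names(spec$positions))
  expect_false("7" %in% names(spec$positions))       # reduced to wt L
  expect_equal(spec$positions[["8"]]$allowed, c("A", "Q", "Y"))
  log <- spec$curation_log
  expect_true(all(c("min_frequency", "distal_conservative",
                    "similarity_collapse", "wt_reinstatement",
                    "wild_type_only") %in% log$rule))
  # curation never increases diversity
  expect_lte(as.numeric(spec$diversity), as.numeric(profile_diversity(prof)))
})

test_that("curation reproduces the published allowed sets from the inverse fixture", {
  tp <- make_toy_profile("table1")
  spec <- curate_profile(tp$profile, tp$rules, fixed_background = "D286R")
  expect_identical(names(spec$positions), names(tp$target$positions))
  for (p in names(spec$positions)) {
    expect_identical(spec$positions[[p]]$allowed,
                     tp$target$positions[[p]]$allowed)
  }
  expect_identical(as.character(spec$diversity), "159252480")
  # audit round-trip: replaying the log on the raw profile reproduces the
  # curated sets
  replayed <- replay_curation_log(tp$profile, spec$curation_log)
  expect_identical(replayed,
                   lapply(spec$positions, function(p) p$allowed))
})

test_that("curation errors when a position empties", {
  seqs <- cbind(`9` = rep(c("A", "G"), c(1, 49)))
  prof <- compile_profile(seqs, wild_type = c(`9` = "G"))
  rules <- curation_rules(min_frequency = 0.05,
                          distal_conservative_removals = list(`9` = "G"))
  expect_error(curate_profile(prof, rules), "curation error.*9")
})

test_that("coverage statistics behave and hit the published regime", {
  tab <- onby_library_table()
  cov <- coverage_fraction(4e9, tab$spec$diversity)
  expect_gt(cov, 0.99)
  expect_equal(coverage_fraction(0, 100), 0)
  expect_equal(coverage_fraction(1, 1), 1)
  # monotone in N, antitone in V, limit 1
  ns <- c(1e6, 1e7, 1e8, 1e9, 1e10)
  cs <- vapply(ns, coverage_fraction, numeric(1), diversity = 1.6e8)
  expect_true(all(diff(cs) > 0))
  vs <- c(1e9, 1e10, 1e11, 1e12)
  cv <- vapply(vs, function(v) coverage_fraction(4e9, v), numeric(1))
  expect_true(all(diff(cv) < 0))
  expect_equal(coverage_fraction(1e18, 1.6e8), 1, tolerance = 1e-12)
})

test_that("orders-of-magnitude reductions match the published bookkeeping", {
  d26 <- theoretical_diversity(26)
  expect_equal(orders_of_magnitude_reduction(d26, 8.4e17), 16L)
  expect_equal(orders_of_magnitude_reduction(d26,
                                             onby_library_table()$spec$diversity),
               26L)
  expect_equal(orders_of_magnitude_reduction(1000, 1000), 0L)
})

test_that("mutation counting matches the published selected variant", {
  tab <- onby_library_table()
  expect_equal(mutation_count(tab$onbyrs1, tab$wild_type), 10L)
  expect_equal(mutation_count(tab$wild_type, tab$wild_type), 0L)
  expect_equal(mutation_count(tab$onbyrs1, tab$wild_type,
                              include_background = TRUE,
                              background = tab$fixed_background), 11L)
  allmut <- stats::setNames(rep("K", length(tab$wild_type)),
                            names(tab$wild_type))
  allmut[tab$wild_type == "K"] <- "R"
  expect_equal(mutation_count(allmut, tab$wild_type), 17L)
  expect_error(mutation_count(c(`999` = "A"), tab$wild_type),
               "reference error")
})

test_that("library export writes the table and guards enumeration", {
  spec <- library_spec(list(`2` = c("A", "S"), `4` = c("G", "Q")),
                       wild_type = c(`2` = "A", `4` = "G"),
                       fixed_background = "D6R")
  dir <- withr::local_tempdir()
  wt <- "MAWGLDE"
  out <- export_library(spec, dir, wt_sequence = wt, enumerate = TRUE)
  expect_true(file.exists(out$tsv))
  tab <- read.delim(out$tsv, colClasses = "character")
  expect_equal(nrow(tab), 2)
  fa <- Biostrings::readAAStringSet(out$fasta)
  expect_length(fa, 4)
  seqs <- as.character(fa)
  # every record carries the fixed background mutation (D6R)
  expect_true(all(substr(seqs, 6, 6) == "R"))
  expect_setequal(substr(seqs, 2, 2), c("A", "S"))
  expect_setequal(substr(seqs, 4, 4), c("G", "Q"))
  # a singleton spec reproduces wild type plus background
  single <- library_spec(list(`2` = "A"), wild_type = c(`2` = "A"),
                         fixed_background = "D6R")
  out1 <- export_library(single, withr::local_tempdir(), wt_sequence = wt,
                         enumerate = TRUE)
  expect_identical(as.character(Biostrings::readAAStringSet(out1$fasta)[[1]]),
                   "MAWGLRE")
  # the published-scale spec refuses enumeration at the default cap
  expect_error(export_library(onby_library_table()$spec,
                              withr::local_tempdir(),
                              wt_sequence = paste(rep("A", 300),
                                                  collapse = ""),
                              enumerate = TRUE),
               "size-guard")
})

test_that("profile diversity of the raw planted profile is the published scale", {
  rp <- make_toy_profile("raw26")
  expect_length(rp$profile$positions, 26)
  expect_identical(as.character(profile_diversity(rp$profile)),
                   "840000000000000000")
  expect_identical(format_sci(profile_diversity(rp$profile)), "8.4e+17")
})
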
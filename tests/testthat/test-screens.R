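test_that("taxonomy assignment uses strict thresholds and best-hit tie-breaks", {
  h <- gen_hit_table(data.frame(
    query = "p1", subject = "Enterobacteria phage CUS-3",
    qcov = 60, pid = 96.04))
  expect_equal(assign_taxonomy(h), "Enterobacteria phage CUS-3")
  # boundary: qcov exactly 50 fails the strict > threshold
  h50 <- gen_hit_table(data.frame(query = "p", subject = "s",
                                  qcov = 50, pid = 99))
  expect_equal(assign_taxonomy(h50), "Unknown")
  h70 <- gen_hit_table(data.frame(query = "p", subject = "s",
                                  qcov = 99, pid = 70))
  expect_equal(assign_taxonomy(h70), "Unknown")
  expect_equal(assign_taxonomy(empty_hit_table()), "Unknown")
  # best hit by bitscore, then pid, then subject id
  multi <- gen_hit_table(data.frame(
    query = "p", subject = c("loser", "winner"),
    qcov = c(60, 80), pid = c(95, 95)))
  expect_equal(assign_taxonomy(multi), "winner")  # longer aln -> higher bitscore
  tie <- gen_hit_table(data.frame(
    query = "p", subject = c("zeta", "alpha"),
    qcov = c(80, 80), pid = c(95, 95)))
  expect_equal(assign_taxonomy(tie), "alpha")
  # taxonomy column wins over subject id when present
  tax <- gen_hit_table(data.frame(query = "p", subject = "acc123",
                                  qcov = 80, pid = 95,
                                  taxonomy = "Siphoviridae sp."))
  expect_equal(assign_taxonomy(tax), "Siphoviridae sp.")
})

test_that("virulence screen keeps >=90/>=90 and deduplicates per prophage", {
  h <- gen_hit_table(data.frame(
    query = c("p1", "p1", "p1", "p2"),
    subject = c("aaiQ", "aaiQ", "sitA", "marA"),
    qcov = 95,
    pid = c(95, 96, 89.9, 92),
    scov = c(92, 95, 99, 89.9)))
  res <- vf_screen(h)
  expect_equal(res$p1, "aaiQ")       # 89.9 pid and 89.9 scov both removed
  expect_false("p2" %in% names(res))
  expect_equal(vf_screen(empty_hit_table()), list())
  # fixture of 10 hits, 3 passing, against a hand-filtered oracle
  set.seed(83)
  fx <- data.frame(query = "px", subject = sprintf("vf%02d", 1:10),
                   qcov = 95,
                   pid = c(95, 91, 90, 85, 89.99, 70, 99, 94, 88, 50),
                   scov = c(95, 90, 89.9, 95, 95, 95, 90, 85, 95, 95))
  keep_by_hand <- fx$subject[fx$pid >= 90 & fx$scov >= 90]
  expect_equal(vf_screen(gen_hit_table(fx))$px, sort(keep_by_hand))
  expect_length(keep_by_hand, 3L)
})

test_that("gut comparison tiers are nested and assigned exactly once", {
  h <- gen_hit_table(data.frame(
    query = c("a", "b", "c", "d", "e"),
    subject = "gut",
    qcov = c(100, 100, 80, 49, 60),
    pid = c(100, 97, 75, 99.9, 60)))
  tiers <- gut_compare(h, c("a", "b", "c", "d", "e", "f"))
  expect_equal(as.character(tiers[c("a", "b", "c", "d", "e", "f")]),
               c("identical", "full_coverage", "match", "none", "none",
                 "none"))
  # the tier predicates are nested: identical satisfies full_coverage etc.
  expect_true(is.ordered(tiers))
  # boundary: full coverage at pid 95.9 drops to match tier
  h2 <- gen_hit_table(data.frame(query = "x", subject = "gut",
                                 qcov = 100, pid = 95.9))
  expect_equal(as.character(gut_compare(h2, "x")), "match")
})

test_that("screens are monotone under threshold sweeps", {
  set.seed(89)
  fx <- gen_hit_table(data.frame(
    query = sprintf("p%02d", 1:40), subject = "db",
    qcov = round(stats::runif(40, 0, 100), 1),
    pid = round(stats::runif(40, 0, 100), 1)))
  prev <- Inf
  for (q in c(0, 25, 50, 75, 100)) {
    cfg <- screen_config(tax_qcov = q)
    n <- sum(assign_taxonomy_all(fx, unique(fx$query_id), cfg) != "Unknown")
    expect_lte(n, prev)
    prev <- n
  }
  prev <- Inf
  for (p in c(0, 50, 70, 90, 100)) {
    cfg <- screen_config(vf_pid = p)
    n <- length(unlist(vf_screen(fx, cfg)))
    expect_lte(n, prev)
    prev <- n
  }
  prev <- Inf
  for (p in c(0, 40, 70, 95, 100)) {
    cfg <- screen_config(gut_pid = p)
    tiers <- gut_compare(fx, unique(fx$query_id), cfg)
    n <- sum(tiers != "none")
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("integrase flagging is a case-insensitive substring match", {
  gt <- data.frame(
    genome_id = c("p1", "p1", "p2", "p3"),
    product = c("site-specific Integrase", "hypothetical protein",
                "hypothetical protein", "integrase core domain protein"))
  flags <- flag_integrase(gt)
  expect_true(flags[["p1"]])
  expect_false(flags[["p2"]])
  expect_true(flags[["p3"]])
})

test_that("resistance-gene tabulation matches a group-by oracle", {
  calls <- data.frame(prophage_id = c("p1", "p2", "p1"),
                      gene_name = c("emrE", "emrE", "marA"))
  res <- arg_tabulate(calls)
  expect_equal(res$frequency$gene_name, c("emrE", "marA"))
  expect_equal(res$frequency$n_prophages, c(2L, 1L))
  expect_equal(res$per_prophage$p1, c("emrE", "marA"))
  empty <- arg_tabulate(calls[0, ])
  expect_length(empty$per_prophage, 0L)
  expect_equal(nrow(empty$frequency), 0L)
  # 100-row synthetic table against an independent group-by
  set.seed(97)
  big <- data.frame(
    prophage_id = sample(sprintf("p%02d", 1:15), 100, replace = TRUE),
    gene_name = sample(c("emrE", "marA", "sul1", "tetA"), 100,
                       replace = TRUE))
  res2 <- arg_tabulate(big)
  oracle <- c(sort(tapply(big$prophage_id, big$gene_name,
                          function(x) length(unique(x))), decreasing = TRUE))
  expect_equal(stats::setNames(res2$frequency$n_prophages,
                               res2$frequency$gene_name)[names(oracle)],
               oracle[names(oracle)])
})

test_that("screens are idempotent on their own output", {
  fx <- gen_hit_table(data.frame(
    query = c("p1", "p1", "p2"), subject = c("vfA", "vfB", "vfA"),
    qcov = 95, pid = c(95, 91, 99), scov = c(95, 92, 99)))
  once <- fx[fx$percent_identity >= 90 & fx$subject_coverage >= 90, ]
  expect_identical(vf_screen(once), vf_screen(fx))
})

test_that("taxonomy labels roll up to morphology family groups", {
  labs <- c("Enterobacteria phage T2 (Myoviridae)", "Podoviridae sp.",
            "Escherichia Siphovirus x", "unclassified Caudovirales",
            "weird phage", "Unknown")
  groups <- taxonomy_rollup(labs)
  expect_equal(unname(groups),
               c("Myoviruses", "Podoviruses", "Siphoviruses",
                 "Unclassified Caudovirales",
                 "Unclassified bacterial viruses", "Unknown"))
})

test_that("blast tabular parsing names columns and flags bad rows", {
  ht <- gen_hit_table(data.frame(query = c("q1", "q2"), subject = "s",
                                 qcov = c(60, 80), pid = c(90, 95)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(ht, path)
  back <- read_blast_tab(path)
  expect_equal(back$query_id, c("q1", "q2"))
  expect_equal(back$query_coverage, c(60, 80))
  expect_equal(back$subject_coverage, c(60, 80))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("q", "s", "oops", rep("1", 9)), collapse = "\t")),
             bad)
  expect_error(read_blast_tab(bad), "line 1")
})
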
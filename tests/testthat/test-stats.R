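test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisherExact2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  sep <- fisherExact2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  expect_true(sep$continuity)

  set.seed(41)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(tab) == 0) next
    got <- fisherExact2x2(tab)
    expect_equal(got$p_value, oracleFisherP(tab), tolerance = 1e-7)
  }
  expect_error(fisherExact2x2(matrix(0, 2, 2)), "all-zero")
  expect_error(fisherExact2x2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("Fisher p is invariant under transpose and row/column swaps", {
  set.seed(42)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisherExact2x2(tab)$p_value
    expect_equal(fisherExact2x2(t(tab))$p_value, p, tolerance = 1e-12)
    expect_equal(fisherExact2x2(tab[2:1, 2:1])$p_value, p,
                 tolerance = 1e-12)
  }
})

test_that("Yates-corrected chi-square matches the textbook formula", {
  flat <- chisqYates(matrix(c(20, 20, 20, 20), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  worked <- chisqYates(matrix(c(30, 10, 10, 30), 2))
  expect_equal(worked$statistic, 18.05, tolerance = 1e-10)

  set.seed(43)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    got <- chisqYates(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((pmax(abs(tab - E) - 0.5, 0))^2 / E)
    expect_equal(got$statistic, stat, tolerance = 1e-9)
    expect_equal(got$p_value, stats::pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
  expect_error(chisqYates(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("Fisher and Yates chi-square agree on large balanced tables", {
  set.seed(44)
  for (i in 1:20) {
    base <- sample(80:150, 4, replace = TRUE)
    tab <- matrix(base, 2)
    pf <- fisherExact2x2(tab)$p_value
    pc <- chisqYates(tab)$p_value
    expect_lt(abs(pf - pc), 0.2 * max(pf, 0.01))
  }
})

test_that("proportion enrichment builds the right table and proportions", {
  bg <- sprintf("g%03d", 1:200)
  ann <- setNames(rep(c(TRUE, FALSE), 100), bg)
  # feature that mirrors the background composition: no signal
  feat_null <- bg[1:40]
  nul <- proportionEnrichment(feat_null, bg, ann)
  expect_gte(nul$result$p_value, 0.5)
  expect_equal(nul$prop_feature, mean(ann[feat_null]))
  expect_equal(nul$prop_background, 0.5)

  # fully annotated feature set against a 50% background
  feat_all <- bg[ann][1:20]
  enr <- proportionEnrichment(feat_all, bg, ann)
  tab <- matrix(c(20, 0, sum(ann) - 20, 100), 2, byrow = TRUE)
  expect_equal(enr$result$p_value, oracleFisherP(tab), tolerance = 1e-9)
  expect_error(proportionEnrichment(character(), bg, ann), "empty")
  expect_error(proportionEnrichment("nope", bg, ann), "subset")
})

test_that("mark-by-methylation proportions equal brute-force counting", {
  set.seed(45)
  n <- 400
  gft <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    methylated_mbt = runif(n) < 0.3,
                    hypomethylated_mbt = FALSE,
                    h3k4me3_mbt = runif(n) < 0.4,
                    h3k9me3_mbt = runif(n) < 0.2,
                    h3k27me3_mbt = runif(n) < 0.25)
  gft$hypomethylated_mbt <- !gft$methylated_mbt & runif(n) < 0.5
  res <- markByMethylationTable(gft, "mbt")
  strat <- ifelse(gft$methylated_mbt, "methylated",
                  ifelse(gft$hypomethylated_mbt, "hypomethylated",
                         "no_me"))
  for (mk in c("h3k4me3", "h3k9me3", "h3k27me3")) {
    row <- res$proportions[res$proportions$mark == mk, ]
    for (st in c("methylated", "hypomethylated", "no_me")) {
      expect_equal(row[[paste0("prop_", st)]],
                   mean(gft[[paste0(mk, "_mbt")]][strat == st]))
    }
    tab <- table(factor(strat, c("methylated", "hypomethylated"))[
                   strat != "no_me"],
                 gft[[paste0(mk, "_mbt")]][strat != "no_me"])
    expect_equal(res$tests[[mk]]$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("marks perfectly aligned with hypomethylation reach the extreme p", {
  n <- 200
  hypo <- rep(c(TRUE, FALSE), each = n / 2)
  gft <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    methylated = !hypo, hypomethylated = hypo,
                    h3k4me3 = hypo, h3k9me3 = FALSE, h3k27me3 = FALSE)
  res <- markByMethylationTable(gft, stage = NULL,
                                marks = "h3k4me3")
  extreme <- fisherExact2x2(matrix(c(0, 100, 100, 0), 2))$p_value
  expect_equal(res$tests$h3k4me3$p_value, extreme, tolerance = 1e-12)
})

test_that("expression by mark and methylation handles extremes and nulls", {
  n <- 120
  marked <- rep(c(TRUE, FALSE), each = n / 2)
  gft <- data.frame(gene_id = seq_len(n), methylated = TRUE,
                    hypomethylated = FALSE, h3k4me3 = marked,
                    expressed_post_zga = marked)  # all marked expressed
  res <- expressionByMarkAndMethylation(gft, stage = NULL,
                                        marks = "h3k4me3")
  cells <- res$cells
  meth_marked <- cells[cells$stratum == "methylated" & cells$marked, ]
  meth_unmarked <- cells[cells$stratum == "methylated" & !cells$marked, ]
  expect_equal(meth_marked$percent_expressed, 100)
  expect_equal(meth_unmarked$percent_expressed, 0)
  expect_lt(res$tests[["methylated:h3k4me3"]]$p_value, 1e-10)
  # empty strata flagged, not fabricated
  expect_true(any(grepl("empty", res$flags)) ||
                all(c("hypomethylated", "no_me") %in% cells$stratum) == FALSE)

  # independence: p should be non-significant most of the time
  set.seed(46)
  ps <- replicate(40, {
    g <- data.frame(gene_id = 1:200, methylated = runif(200) < 0.5,
                    hypomethylated = FALSE,
                    h3k4me3 = runif(200) < 0.5,
                    expressed_post_zga = runif(200) < 0.5)
    r <- expressionByMarkAndMethylation(g, NULL, "h3k4me3")
    r$tests[["methylated:h3k4me3"]]$p_value
  })
  expect_lt(mean(ps <= 0.05), 0.2)
})

test_that("set overlap reports are exact Venn algebra", {
  a <- sprintf("g%02d", 1:30)
  same <- setOverlapReport(list(x = a, y = a))
  expect_equal(unname(same$regions["11"]), 30L)
  expect_equal(unname(same$percent_of_set$x["11"]), 100)
  expect_equal(unname(same$jaccard["x|y"]), 1)

  disj <- setOverlapReport(list(x = a[1:10], y = a[11:30]))
  expect_equal(unname(disj$regions["11"]), 0L)
  expect_equal(unname(disj$jaccard["x|y"]), 0)

  set.seed(47)
  for (i in 1:10) {
    u <- sprintf("g%03d", 1:100)
    s1 <- sample(u, 40); s2 <- sample(u, 55); s3 <- sample(u, 25)
    rep3 <- setOverlapReport(list(a = s1, b = s2, c = s3))
    expect_equal(sum(rep3$regions), length(union(union(s1, s2), s3)))
    expect_equal(unname(rep3$regions["111"]),
                 length(intersect(intersect(s1, s2), s3)))
    expect_equal(sum(rep3$regions[substr(names(rep3$regions), 2, 2) ==
                                    "1"]), 55L)
    expect_equal(unname(rep3$jaccard["a|b"]),
                 length(intersect(s1, s2)) / length(union(s1, s2)))
  }
})
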
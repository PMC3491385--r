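#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value with the probability-mass extremity criterion
#' (tables as or less probable than the observed one under the
#' hypergeometric null), plus the sample odds ratio.  When a cell is zero
#' the odds ratio gets the Haldane 0.5 continuity addition and the result
#' is flagged.
#'
#' @param tab 2x2 matrix (or something coercible) of non-negative integer
#'   counts; at least one margin must be positive.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a `ContingencyResult` list: `table`, `odds_ratio`, `p_value`,
#'   `test`, `alternative`, `continuity`.
#' @examples
#' fisherExact2x2(matrix(c(10, 0, 0, 10), 2))
#' @export
fisherExact2x2 <- function(tab, alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  tab <- validate2x2(tab)
  if (sum(tab) == 0) stop("all-zero 2x2 table")
  ft <- fisher.test(tab, alternative = alternative)
  continuity <- any(tab == 0)
  t2 <- if (continuity) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  structure(list(table = tab, odds_ratio = unname(or),
                 p_value = unname(ft$p.value), test = "fisher_exact",
                 alternative = alternative, continuity = continuity),
            class = "ContingencyResult")
}

#' Chi-square test with Yates' continuity correction on a 2x2 table
#'
#' `chi^2 = sum((|O - E| - 0.5)^2 / E)` with the correction floored so it
#' never overshoots `|O - E|`; p from the chi-square distribution with one
#' degree of freedom.
#'
#' @param tab 2x2 matrix of non-negative counts; all margins must be
#'   positive.
#' @return a `ContingencyResult` list with `statistic` in addition to the
#'   [fisherExact2x2()] fields.
#' @examples
#' chisqYates(matrix(c(30, 10, 10, 30), 2))  # statistic 18.05
#' @export
chisqYates <- function(tab) {
  tab <- validate2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square with Yates correction needs all margins > 0")
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  continuity <- any(tab == 0)
  t2 <- if (continuity) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  structure(list(table = tab, statistic = unname(ct$statistic),
                 odds_ratio = unname(or), p_value = unname(ct$p.value),
                 test = "chisq_yates", alternative = "two.sided",
                 continuity = continuity),
            class = "ContingencyResult")
}

validate2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  storage.mode(tab) <- "double"
  tab
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("%s (%s): p = %.4g, odds ratio = %.3f%s\n", x$test,
              x$alternative, x$p_value, x$odds_ratio,
              if (isTRUE(x$continuity)) " [0.5 continuity]" else ""))
  print(x$table)
  invisible(x)
}

#' Enrichment of an annotation in a gene set over its background
#'
#' Builds the 2x2 table (in / out of the feature set) x (annotated / not)
#' and applies Fisher's exact test; the pattern used to ask, for example,
#' whether hypomethylated promoters are enriched in high-CpG promoters
#' relative to all genes.
#'
#' @param featureGenes character vector, a subset of `backgroundGenes`.
#' @param backgroundGenes the gene universe.
#' @param annotation named logical over (at least) the universe.
#' @param alternative passed to [fisherExact2x2()].
#' @return list: `result` (a `ContingencyResult`), `prop_feature`,
#'   `prop_background` (proportion annotated in the full universe),
#'   `table`.
#' @export
proportionEnrichment <- function(featureGenes, backgroundGenes, annotation,
                                 alternative = "two.sided") {
  if (!length(featureGenes)) stop("empty feature set")
  if (!all(featureGenes %in% backgroundGenes))
    stop("feature set must be a subset of the background")
  ann <- annotation[backgroundGenes]
  if (any(is.na(ann))) stop("annotation missing for some background genes")
  inset <- backgroundGenes %in% featureGenes
  tab <- matrix(c(sum(ann[inset]), sum(!ann[inset]),
                  sum(ann[!inset]), sum(!ann[!inset])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("feature", "rest"),
                                c("annotated", "not_annotated")))
  list(result = fisherExact2x2(tab, alternative = alternative),
       prop_feature = mean(ann[inset]), prop_background = mean(ann),
       table = tab)
}

# Strata used by the integration tables: statistically methylated,
# statistically hypomethylated, or neither ("no_me", the genome-average
# stratum).  Conflicting genes (both TRUE) are dropped with a warning.
methylationStrata <- function(gft, stage) {
  mcol <- stageColumn(gft, "methylated", stage)
  hcol <- stageColumn(gft, "hypomethylated", stage)
  meth <- asLogicalCall(gft[[mcol]])
  hypo <- asLogicalCall(gft[[hcol]])
  conflict <- meth & hypo
  if (any(conflict, na.rm = TRUE))
    warning(sum(conflict, na.rm = TRUE),
            " gene(s) flagged both methylated and hypomethylated; dropped")
  strat <- ifelse(conflict, NA_character_,
                  ifelse(meth, "methylated",
                         ifelse(hypo, "hypomethylated", "no_me")))
  factor(strat, levels = c("methylated", "hypomethylated", "no_me"))
}

stageColumn <- function(gft, base, stage) {
  cand <- c(paste(base, stage, sep = "_"), base)
  hit <- cand[cand %in% names(gft)]
  if (!length(hit))
    stop("no column '", cand[1], "' (or '", base, "') in the gene table")
  hit[1]
}

asLogicalCall <- function(x) {
  if (is.logical(x)) return(x)
  as.character(x) == "yes" | as.character(x) == "TRUE"
}

#' Histone-mark proportions by promoter methylation stratum
#'
#' Splits genes into the three mutually exclusive methylation strata
#' (methylated / hypomethylated / genome-average `no_me`) and reports, per
#' histone mark, the proportion of marked promoters in each stratum plus a
#' Fisher test comparing the methylated and hypomethylated strata.
#'
#' @param gft gene feature table (`data.frame`), with logical mark columns
#'   (`<mark>` or `<mark>_<stage>`) and methylation state columns
#'   (`methylated[_<stage>]`, `hypomethylated[_<stage>]`).
#' @param stage stage suffix used to pick columns; `NULL` for unsuffixed.
#' @param marks mark column base names.
#' @return list: `proportions` (mark x stratum data.frame with counts),
#'   `tests` (per-mark `ContingencyResult`s, methylated vs hypomethylated),
#'   `flags` (character notes, e.g. empty strata).
#' @export
markByMethylationTable <- function(gft, stage = NULL,
                                   marks = c("h3k4me3", "h3k9me3",
                                             "h3k27me3")) {
  strat <- methylationStrata(gft, stage)
  flags <- character()
  empty <- levels(strat)[table(strat) == 0]
  if (length(empty))
    flags <- c(flags, paste("empty stratum:", empty))
  prop_rows <- list(); tests <- list()
  for (mk in marks) {
    v <- asLogicalCall(gft[[stageColumn(gft, mk, stage)]])
    agg <- tapply(v, strat, function(z) c(n = length(z), marked = sum(z)))
    row <- data.frame(mark = mk)
    for (st in levels(strat)) {
      a <- agg[[st]]
      row[[paste0("prop_", st)]] <- if (!is.null(a) && a["n"] > 0)
        unname(a["marked"] / a["n"]) else NA_real_
      row[[paste0("n_", st)]] <- if (!is.null(a)) unname(a["n"]) else 0L
    }
    prop_rows[[mk]] <- row
    am <- agg[["methylated"]]; ah <- agg[["hypomethylated"]]
    if (!is.null(am) && !is.null(ah) && am["n"] > 0 && ah["n"] > 0) {
      tab <- matrix(c(am["marked"], am["n"] - am["marked"],
                      ah["marked"], ah["n"] - ah["marked"]),
                    nrow = 2, byrow = TRUE,
                    dimnames = list(c("methylated", "hypomethylated"),
                                    c("marked", "unmarked")))
      tests[[mk]] <- fisherExact2x2(tab)
    } else {
      flags <- c(flags, paste("no test for", mk,
                              "(missing methylation stratum)"))
    }
  }
  list(proportions = do.call(rbind,
                             c(prop_rows, list(make.row.names = FALSE))),
       tests = tests, flags = flags)
}

#' Post-ZGA expression by methylation state and histone marking
#'
#' For each methylation stratum and each mark, the percentage of genes
#' expressed after zygotic genome activation among marked versus unmarked
#' promoters, with a Yates-corrected chi-square test per (stratum, mark)
#' pair.  Cells with no genes, or pairs with a zero margin, are excluded
#' and flagged.
#'
#' @inheritParams markByMethylationTable
#' @param expressedCol base name of the logical expression column
#'   (default `"expressed_post_zga"`).
#' @return list: `cells` (stratum x mark x marked/unmarked percentages and
#'   counts), `tests` (named `ContingencyResult`s `"<stratum>:<mark>"`),
#'   `flags`.
#' @export
expressionByMarkAndMethylation <- function(gft, stage = NULL,
                                           marks = c("h3k4me3", "h3k9me3",
                                                     "h3k27me3"),
                                           expressedCol =
                                             "expressed_post_zga") {
  strat <- methylationStrata(gft, stage)
  expr <- asLogicalCall(gft[[stageColumn(gft, expressedCol, stage)]])
  cells <- list(); tests <- list(); flags <- character()
  for (st in levels(strat)) {
    in_st <- !is.na(strat) & strat == st
    for (mk in marks) {
      v <- asLogicalCall(gft[[stageColumn(gft, mk, stage)]])
      for (marked in c(TRUE, FALSE)) {
        sel <- in_st & (v == marked)
        key <- sprintf("%s:%s:%s", st, mk,
                       if (marked) "marked" else "unmarked")
        if (!any(sel)) {
          flags <- c(flags, paste("empty cell", key))
          next
        }
        cells[[key]] <- data.frame(stratum = st, mark = mk,
                                   marked = marked, n = sum(sel),
                                   percent_expressed =
                                     100 * mean(expr[sel]))
      }
      tab <- table(factor(v[in_st], levels = c(TRUE, FALSE)),
                   factor(expr[in_st], levels = c(TRUE, FALSE)))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        tests[[paste(st, mk, sep = ":")]] <- chisqYates(tab)
      } else {
        flags <- c(flags, paste("no test for", st, mk, "(zero margin)"))
      }
    }
  }
  list(cells = do.call(rbind, c(cells, list(make.row.names = FALSE))),
       tests = tests, flags = flags)
}

#' Venn-style overlap report for named gene sets
#'
#' All region counts of the 2- or 3-set Venn partition, percentages of
#' each set falling in each region, and pairwise Jaccard indices.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return list with `regions` (named counts), `percent_of_set`,
#'   `jaccard`, `union_size`.
#' @export
setOverlapReport <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L) stop("supply 2 or 3 named sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1L, function(z) paste(ifelse(z, "1", "0"),
                                               collapse = ""))
  all_patterns <- apply(expand.grid(rep(list(c("1", "0")), k)), 1L, paste,
                        collapse = "")
  all_patterns <- setdiff(all_patterns, paste(rep("0", k), collapse = ""))
  regions <- setNames(integer(length(all_patterns)), all_patterns)
  tb <- table(pattern)
  regions[names(tb)] <- as.integer(tb)
  percent <- lapply(seq_len(k), function(i) {
    in_i <- names(regions)[substr(names(regions), i, i) == "1"]
    n_i <- length(sets[[i]])
    setNames(if (n_i) 100 * regions[in_i] / n_i else regions[in_i] * NA,
             in_i)
  })
  names(percent) <- names(sets)
  jac <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    key <- paste(names(sets)[i], names(sets)[j], sep = "|")
    u <- length(union(sets[[i]], sets[[j]]))
    jac[[key]] <- if (u) length(intersect(sets[[i]], sets[[j]])) / u else NA
  }
  list(regions = regions, percent_of_set = percent,
       jaccard = unlist(jac), union_size = length(universe),
       set_sizes = lengths(sets))
}
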
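#' Mendelian segregation goodness-of-fit test
#'
#' Pearson chi-squared test of observed dominant/recessive counts against an
#' expected ratio (default 3:1), without continuity correction, df = 1.
#'
#' @param n_dominant,n_recessive Observed counts (total > 0).
#' @param ratio Length-2 expected ratio, dominant first.
#' @return An object of class `segregation_result`: `observed`, `expected`,
#'   `ratio`, `chi_square`, `p_value`, `df`.
#' @export
segregation_test <- function(n_dominant, n_recessive, ratio = c(3, 1)) {
  stopifnot(n_dominant >= 0, n_recessive >= 0,
            n_dominant + n_recessive > 0, length(ratio) == 2L,
            all(ratio > 0))
  obs <- c(dominant = n_dominant, recessive = n_recessive)
  ht <- suppressWarnings(stats::chisq.test(obs, p = ratio / sum(ratio),
                                           correct = FALSE))
  structure(list(observed = obs, expected = unname(ht$expected),
                 ratio = ratio, chi_square = unname(ht$statistic),
                 p_value = ht$p.value, df = 1L),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(paste0("<segregation_result> %d:%d vs %g:%g -> ",
                     "chi-square = %.2f, p = %.3g (df = 1)\n"),
              x$observed[1L], x$observed[2L], x$ratio[1L], x$ratio[2L],
              x$chi_square, x$p_value))
  invisible(x)
}

#' Allele frequency among diploid accessions
#'
#' `carriers * copies_per_carrier / (2 * population) * 100`, with the
#' reported value rounded half-up to an integer percent (the convention in
#' survey reporting; e.g. 71 carriers of 528 diploids -> 6.72% -> 7%).
#'
#' @param carriers Number of accessions carrying the allele.
#' @param population Number of diploid accessions surveyed (> 0).
#' @param copies_per_carrier Allele copies assumed per carrier (default 1).
#' @return List with `percent` (exact) and `percent_reported` (integer).
#' @export
allele_frequency <- function(carriers, population, copies_per_carrier = 1) {
  stopifnot(population > 0, carriers >= 0, carriers <= population,
            copies_per_carrier %in% c(1, 2))
  pct <- carriers * copies_per_carrier / (2 * population) * 100
  list(percent = pct, percent_reported = round_half_up(pct))
}

round_half_up <- function(x) floor(x + 0.5)

#' Marker-presence x berry-phenotype contingency analysis
#'
#' Cross-tabulates a presence/absence marker call against phenotype classes
#' and tests the 2x2 collapse (black vs non-black) with Fisher's exact
#' test. Perfect separation (every marker-positive accession black, no
#' marker-negative accession black) is flagged.
#'
#' @param calls Named logical vector: marker presence per accession.
#' @param phenotypes Named character/factor vector over the same
#'   accessions, with levels among `black`, `light`, `white`.
#' @return List with `table` (2 x k), `fisher_p`, `perfect_separation`.
#' @export
phenotype_contingency <- function(calls, phenotypes) {
  stopifnot(!is.null(names(calls)), !is.null(names(phenotypes)))
  if (!setequal(names(calls), names(phenotypes))) {
    stop("accession sets of calls and phenotypes differ")
  }
  phenotypes <- phenotypes[names(calls)]
  ph <- factor(as.character(phenotypes),
               levels = intersect(c("black", "light", "white"),
                                  unique(as.character(phenotypes))))
  tab <- table(marker = factor(ifelse(calls, "present", "absent"),
                               levels = c("present", "absent")),
               phenotype = ph)
  black <- as.character(phenotypes) == "black"
  t2 <- table(factor(calls, levels = c(TRUE, FALSE)),
              factor(black, levels = c(TRUE, FALSE)))
  p <- stats::fisher.test(t2)$p.value
  sep <- sum(calls & !black) == 0L && sum(!calls & black) == 0L &&
    any(calls) && any(!calls)
  list(table = tab, fisher_p = p, perfect_separation = sep)
}

#' Haplotype-dosage effect on anthocyanin content
#'
#' Welch two-sample comparison of anthocyanin content (mg/L) between
#' genotypes carrying two functional haplotypes at the color locus and
#' genotypes carrying one; the effect is reported as the percent difference
#' of group means, `(mean2 - mean1) / mean1 * 100`.
#'
#' @param values_2copy,values_1copy Numeric vectors (each n >= 2).
#' @return An object of class `dosage_comparison`: group means, `percent`,
#'   `statistic`, `p_value`.
#' @export
dosage_comparison <- function(values_2copy, values_1copy) {
  stopifnot(length(values_2copy) >= 2L, length(values_1copy) >= 2L)
  m2 <- mean(values_2copy); m1 <- mean(values_1copy)
  if (stats::sd(values_2copy) == 0 && stats::sd(values_1copy) == 0) {
    # degenerate constant groups: no variance to test against
    ht <- list(statistic = c(t = if (m2 == m1) 0 else Inf),
               p.value = if (m2 == m1) 1 else 0,
               parameter = c(df = NA_real_))
  } else {
    ht <- stats::t.test(values_2copy, values_1copy)
  }
  structure(list(mean_2copy = m2, mean_1copy = m1,
                 percent = (m2 - m1) / m1 * 100,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 df = unname(ht$parameter)),
            class = "dosage_comparison")
}

#' @export
print.dosage_comparison <- function(x, ...) {
  cat(sprintf(paste0("<dosage_comparison> 2 copies: %.1f mg/L, 1 copy: ",
                     "%.1f mg/L (%+.0f%%), Welch p = %.3g\n"),
              x$mean_2copy, x$mean_1copy, x$percent, x$p_value))
  invisible(x)
}

#' Aggregate a haplotype survey table
#'
#' Per-region detection frequency (integer percent, half-up, `NA` where
#' nothing was detected -- printed as "Not detected") and the grand total of
#' detections.
#'
#' @param table data.frame with columns `region`, `examined`, `detected`.
#' @return List with `table` (adding `frequency_percent`) and
#'   `total_detected`.
#' @export
aggregate_survey <- function(table) {
  stopifnot(all(c("region", "examined", "detected") %in% names(table)),
            all(table$detected >= 0), all(table$detected <= table$examined))
  pct <- ifelse(table$detected > 0,
                round_half_up(table$detected / table$examined * 100),
                NA_integer_)
  out <- table
  out$frequency_percent <- as.integer(pct)
  list(table = out, total_detected = sum(table$detected))
}

#' The HapF1 wild-grapevine WGS survey counts
#'
#' Numbers of *V. vinifera* subsp. *sylvestris* WGS datasets examined and
#' found to carry HapF1, by region of origin (the west-to-east gradient:
#' absent across Europe, frequent from the Levant through the Caucasus).
#'
#' @return data.frame with `region`, `examined`, `detected`.
#' @export
hapf1_survey <- function() {
  utils::read.table(system.file("extdata", "hapf1_survey.tsv",
                                package = "bclhap"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
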
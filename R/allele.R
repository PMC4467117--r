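#' Per-allele quantification units for one sample
#'
#' Holds the integer quantification units (e.g. electropherogram peak areas
#' scaled to counts) for the two alleles of a heterozygous site in one
#' sample (input chromatin, ChIP eluate, ...). Continuous areas must be
#' scaled to integers because the downstream exact test is count-based:
#' `scale` multiplies before rounding, and the rounding is reported so the
#' choice of scale stays visible.
#'
#' @param label sample name, e.g. `"input"` or `"ChIP"`.
#' @param units_a,units_g non-negative quantification units for the two
#'   alleles (generalised ref/alt; named after the A/G site they were
#'   first used for).
#' @param scale multiplier applied before rounding to integer (default 1).
#' @return an object of class `AlleleCounts` with integer `units_a`,
#'   `units_g`.
#' @examples
#' allele_counts("input", 632, 368)
#' @export
allele_counts <- function(label, units_a, units_g, scale = 1) {
  stopifnot(units_a >= 0, units_g >= 0, scale > 0)
  a <- round(units_a * scale); g <- round(units_g * scale)
  if (a + g <= 0) stop("allele_counts: units_a + units_g must be > 0")
  structure(list(label = as.character(label), units_a = a, units_g = g),
            class = "AlleleCounts")
}

#' @export
print.AlleleCounts <- function(x, ...) {
  cat(sprintf("AlleleCounts '%s': A=%d G=%d (A fraction %.1f%%)\n",
              x$label, x$units_a, x$units_g, allele_fraction(x)))
  invisible(x)
}

#' Allele fraction as a percentage
#'
#' The normalisation used for electropherogram areas:
#' `(A / (A + G)) * 100`.
#'
#' @param counts an [allele_counts()] object, or the A units when `units_g`
#'   is given.
#' @param units_g G units (when `counts` is the A units).
#' @return percentage of the A allele, in `[0, 100]`.
#' @examples
#' allele_fraction(632, 368)  # 63.2
#' @export
allele_fraction <- function(counts, units_g = NULL) {
  if (is(counts, "AlleleCounts")) {
    a <- counts$units_a; g <- counts$units_g
  } else {
    a <- counts; g <- units_g
  }
  stopifnot(a >= 0, g >= 0)
  if (a + g <= 0) stop("allele_fraction: total units must be > 0")
  100 * a / (a + g)
}

check_count <- function(x, what) {
  if (abs(x - round(x)) > 1e-8)
    stop(sprintf("fisher_allele_test: %s = %s is not an integer; scale your quantification units to counts first (see allele_counts(scale=))",
                 what, format(x)))
  if (x < 0) stop("fisher_allele_test: negative cell ", what)
  as.numeric(round(x))
}

# two-sided exact p for a 2x2 table with fixed margins, probability
# ordering: sum hypergeometric masses <= the observed mass (relative
# tolerance 1e-7, the convention of conditional exact tests)
fisher_p2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  supp <- lo:hi
  dens <- dhyper(supp, m, n, k)
  pobs <- dens[supp == a]
  min(1, sum(dens[dens <= pobs * (1 + 1e-7)]))
}

#' Fisher's exact test for allele-specific binding
#'
#' Compares the allele balance of the ChIP sample against the input
#' chromatin in a 2x2 table (rows: input/ChIP; columns: allele A/G) using
#' the two-sided exact test (probability ordering: the p-value sums the
#' hypergeometric probabilities, at the observed margins, of every table
#' at most as probable as the observed one). The odds ratio is the
#' cross-product ratio `(a*d)/(b*c)`; zero cells yield `Inf` or `0` (and
#' `NaN` when both products vanish), never an error.
#'
#' @param input,chip [allele_counts()] objects (or numeric `c(A, G)`
#'   pairs).
#' @return a list of class `AlleleSpecificResult`: `fraction_a_pct` (named
#'   per-sample A-allele percentages), `p_value`, `odds_ratio`, `table`.
#' @examples
#' r <- fisher_allele_test(c(10, 0), c(0, 10))
#' r$p_value  # 2/184756
#' @export
fisher_allele_test <- function(input, chip) {
  as_pair <- function(x, label) {
    if (inherits(x, "AlleleCounts")) return(x)
    # raw numeric pairs are NOT rounded here: non-integer units must
    # surface as an error pointing at the scaling decision
    stopifnot(length(x) == 2, all(x >= 0))
    list(label = label, units_a = x[1], units_g = x[2])
  }
  input <- as_pair(input, "input"); chip <- as_pair(chip, "ChIP")
  a <- check_count(input$units_a, "input A")
  b <- check_count(input$units_g, "input G")
  c_ <- check_count(chip$units_a, "ChIP A")
  d <- check_count(chip$units_g, "ChIP G")
  if (a + b <= 0 || c_ + d <= 0)
    stop("fisher_allele_test: each sample needs a positive total")
  or <- if (b * c_ > 0) (a * d) / (b * c_)
        else if (a * d > 0) Inf else NaN
  labels <- c(input$label, chip$label)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(labels, c("A", "G")))
  frac <- c(100 * a / (a + b), 100 * c_ / (c_ + d))
  names(frac) <- labels
  structure(list(
    fraction_a_pct = frac,
    p_value = fisher_p2(a, b, c_, d),
    odds_ratio = or,
    table = tab), class = "AlleleSpecificResult")
}

#' @export
print.AlleleSpecificResult <- function(x, ...) {
  f <- x$fraction_a_pct
  cat(sprintf("Allele-specific test: A%% %s=%.1f, %s=%.1f; OR=%.3g; two-sided Fisher p=%.3g\n",
              names(f)[1], f[1], names(f)[2], f[2], x$odds_ratio, x$p_value))
  invisible(x)
}

# ---- qPCR quantification ---------------------------------------------------

check_ct <- function(ct, cols) {
  stopifnot(is.data.frame(ct), all(cols %in% names(ct)))
  if (any(!is.finite(ct$ct) | ct$ct <= 0))
    stop("Ct table: Ct values must be finite and > 0")
  ct
}

mean_ct <- function(ct, gene, condition) {
  v <- ct$ct[ct$gene == gene & ct$condition == condition]
  if (!length(v))
    stop(sprintf("Ct table: no rows for gene '%s' in condition '%s'",
                 gene, condition))
  mean(v)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = mean Ct(target) - mean over reference genes of their mean Ct`
#' (arithmetic mean of Cts, i.e. geometric mean of reference quantities);
#' `ddCt = dCt(condition) - dCt(control)`; fold change `= 2^(-ddCt)`,
#' assuming 2-fold amplification per cycle. Replicate Cts are averaged
#' before dCt; replicate spread of the target in `condition` is reported
#' as `sd_log2` (cycles) but does not enter the point estimate.
#'
#' @param ct a Ct table `data.frame` with columns `gene`, `condition`,
#'   `replicate`, `ct`.
#' @param target target gene name.
#' @param reference_genes character vector of reference genes (>= 1), e.g.
#'   `c("GAPDH", "B2M")`.
#' @param condition,control condition names; fold change is `condition`
#'   relative to `control`.
#' @return a list of class `DdctResult`: `fold_change`, `ddct`,
#'   `dct_condition`, `dct_control`, `sd_log2`.
#' @examples
#' ct <- data.frame(gene = rep(c("T", "GAPDH", "B2M"), 2),
#'                  condition = rep(c("EtOH", "DHT"), each = 3),
#'                  replicate = 1,
#'                  ct = c(25, 20, 22, 24, 20, 22))
#' ddct_expression(ct, "T", c("GAPDH", "B2M"), "DHT", "EtOH")$fold_change  # 2
#' @export
ddct_expression <- function(ct, target, reference_genes, condition, control) {
  ct <- check_ct(ct, c("gene", "condition", "replicate", "ct"))
  stopifnot(length(reference_genes) >= 1)
  ref_ct <- function(cond)
    mean(vapply(reference_genes, mean_ct, 0, ct = ct, condition = cond))
  dct <- function(cond) mean_ct(ct, target, cond) - ref_ct(cond)
  ddct <- dct(condition) - dct(control)
  reps <- ct$ct[ct$gene == target & ct$condition == condition]
  structure(list(fold_change = 2^(-ddct), ddct = ddct,
                 dct_condition = dct(condition), dct_control = dct(control),
                 sd_log2 = if (length(reps) > 1) sd(reps) else NA_real_),
            class = "DdctResult")
}

#' @export
print.DdctResult <- function(x, ...) {
  cat(sprintf("ddCt = %.3f -> fold change %.3g (target replicate sd %.2f cycles)\n",
              x$ddct, x$fold_change, x$sd_log2))
  invisible(x)
}

#' Percent-input ChIP-qPCR enrichment
#'
#' ChIP signal as a percentage of input chromatin, adjusted for the
#' fraction of material kept as input: with a 10% input aliquot the input
#' Ct is shifted by `-log2(0.10)` (about +3.32 cycles) before comparison,
#' and `%input = 100 * 2^(adjusted input Ct - ChIP Ct)`. Each condition's
#' percent input is also reported relative to the control condition (e.g.
#' vehicle-treated cells).
#'
#' @param ct a `data.frame` with columns `condition`, `sample` (`"chip"` or
#'   `"input"`), `replicate`, `ct`; replicates are averaged.
#' @param input_fraction fraction of sample kept as input, in `(0, 1]`
#'   (default 0.10).
#' @param control_condition condition the final column is normalised to.
#' @return a `data.frame` with one row per condition: `condition`,
#'   `percent_input`, `relative_to_control`.
#' @export
percent_input <- function(ct, input_fraction = 0.10, control_condition) {
  ct <- check_ct(ct, c("condition", "sample", "replicate", "ct"))
  if (!(input_fraction > 0 && input_fraction <= 1))
    stop("percent_input: input_fraction must be in (0, 1]")
  conds <- unique(ct$condition)
  if (!control_condition %in% conds)
    stop("percent_input: control condition '", control_condition,
         "' not in Ct table")
  pct <- vapply(conds, function(cond) {
    chip <- ct$ct[ct$condition == cond & ct$sample == "chip"]
    inp <- ct$ct[ct$condition == cond & ct$sample == "input"]
    if (!length(chip) || !length(inp))
      stop("percent_input: condition '", cond,
           "' needs both chip and input Ct values")
    adj_input <- mean(inp) - log2(input_fraction)
    100 * 2^(adj_input - mean(chip))
  }, 0)
  data.frame(condition = conds, percent_input = unname(pct),
             relative_to_control = unname(pct / pct[conds == control_condition]),
             stringsAsFactors = FALSE)
}
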
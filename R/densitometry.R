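# Hounsfield-based osteoporosis scoring and comparative study arithmetic.
#
# The T' score transplants the clinical DXA T-score onto CT values,
# relying on the linear CT-BMD relation:
#   T' = (measured CT value - reference mean) / reference SD,
# with osteoporosis defined at T' <= -2.5 (inclusive threshold).

#' T-prime osteoporosis score
#'
#' @param ct_value Measured mean CT value (HU) of the vertebra.
#' @param ref_mean,ref_sd Mean and standard deviation (HU) of the normal
#'   reference population; `ref_sd > 0`.
#' @return An object of class `tprime_result` with fields `ct_value`,
#'   `ref_mean`, `ref_sd`, `t_prime` and `osteoporotic`
#'   (`t_prime <= -2.5`).
#' @export
t_prime <- function(ct_value, ref_mean, ref_sd) {
  if (ref_sd <= 0) stop("ref_sd must be > 0")
  tp <- (ct_value - ref_mean) / ref_sd
  structure(list(ct_value = ct_value, ref_mean = ref_mean,
                 ref_sd = ref_sd, t_prime = tp,
                 osteoporotic = tp <= -2.5),
            class = "tprime_result")
}

#' @export
print.tprime_result <- function(x, ...) {
  cat(sprintf("T' = %.2f (CT %.2f HU vs reference %.2f +/- %.2f HU)%s\n",
              x$t_prime, x$ct_value, x$ref_mean, x$ref_sd,
              if (x$osteoporotic) " -- osteoporotic" else ""))
  invisible(x)
}

#' Group summary (mean +/- sample SD)
#'
#' @param n Group size (>= 2 when `sd` is given).
#' @param mean Group mean.
#' @param sd Sample standard deviation (n - 1 denominator), >= 0.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (sd < 0) stop("sd must be >= 0")
  if (!is.na(sd) && n < 2) stop("n must be >= 2 for a sample sd")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' T-prime transform of group statistics
#'
#' By linearity of the score, a group with mean m and sd s maps to
#' T' mean `(m - ref_mean)/ref_sd` and T' sd `s/ref_sd`.
#'
#' @param g A [group_summary()] (or list with `mean`, `sd`).
#' @param ref_mean,ref_sd Reference statistics (HU); `ref_sd > 0`.
#' @return List with `t_prime_mean` and `t_prime_sd`.
#' @export
tprime_of_group <- function(g, ref_mean, ref_sd) {
  if (ref_sd <= 0) stop("ref_sd must be > 0")
  list(t_prime_mean = (g$mean - ref_mean) / ref_sd,
       t_prime_sd = g$sd / ref_sd)
}

#' Percent difference relative to a baseline
#'
#' `100 * (a - b) / b`; identically `percent_of(a, b) - 100`.
#'
#' @param a Value.
#' @param b Baseline (nonzero).
#' @return Percent difference.
#' @export
percent_difference <- function(a, b) {
  if (b == 0) stop("zero baseline")
  100 * (a - b) / b
}

#' Percent of a reference value
#'
#' `100 * a / b`.
#'
#' @param a Value.
#' @param b Reference (nonzero).
#' @return Percentage.
#' @export
percent_of <- function(a, b) {
  if (b == 0) stop("zero reference")
  100 * a / b
}

.require_group <- function(groups, name, quantity) {
  row <- groups[groups$group == name & groups$quantity == quantity, ,
                drop = FALSE]
  if (nrow(row) == 0L)
    stop("missing group '", name, "' (", quantity, ")")
  row[1, ]
}

#' Comparative study report from group summaries
#'
#' Reproduces the derived arithmetic of a two-arm (automatic vs manual
#' planning) decalcified-vs-control study: T' transforms of the HU
#' groups against the reference population, the automatic-vs-manual and
#' control-vs-decalcified percent comparisons for trajectory HU and
#' pull-out force, and the automatic/control pull-out ratio. T' values
#' are reported to two decimals, percentages to one.
#'
#' @param groups Data frame with columns `group`, `quantity`
#'   (`"hu"` or `"newton"`), `n`, `mean`, `sd`. Required rows:
#'   `reference` (hu), `decal_ap`, `decal_mp`, `control_mp`
#'   (hu and, where available, newton).
#' @return An object of class `study_report`: list with `tprime` (data
#'   frame) and `comparisons` (data frame with `name`, `quantity`,
#'   `value_pct`).
#' @export
study_report <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("group", "quantity", "n", "mean", "sd") %in%
                  names(groups)))
  ref <- .require_group(groups, "reference", "hu")
  hu_names <- c("decal_ap", "decal_mp", "control_mp")
  tp <- do.call(rbind, lapply(hu_names, function(nm) {
    g <- .require_group(groups, nm, "hu")
    z <- tprime_of_group(g, ref$mean, ref$sd)
    data.frame(group = nm, n = g$n, mean_hu = g$mean, sd_hu = g$sd,
               t_prime_mean = round(z$t_prime_mean, 2),
               t_prime_sd = round(z$t_prime_sd, 2),
               osteoporotic = z$t_prime_mean <= -2.5)
  }))

  cmp <- function(name, quantity, value)
    data.frame(name = name, quantity = quantity,
               value_pct = round(value, 1))
  ap_hu <- .require_group(groups, "decal_ap", "hu")
  mp_hu <- .require_group(groups, "decal_mp", "hu")
  ctl_hu <- .require_group(groups, "control_mp", "hu")
  comparisons <- rbind(
    cmp("hu_ap_vs_mp", "hu",
        percent_difference(ap_hu$mean, mp_hu$mean)),
    cmp("hu_ap_vs_control_mp", "hu",
        percent_difference(ap_hu$mean, ctl_hu$mean)))

  has_force <- all(vapply(
    c("decal_ap", "decal_mp", "control_mp"),
    function(nm) nrow(groups[groups$group == nm &
                               groups$quantity == "newton", ]) > 0,
    logical(1)))
  if (has_force) {
    ap_f <- .require_group(groups, "decal_ap", "newton")
    mp_f <- .require_group(groups, "decal_mp", "newton")
    ctl_f <- .require_group(groups, "control_mp", "newton")
    comparisons <- rbind(
      comparisons,
      cmp("pullout_ap_vs_mp", "newton",
          percent_difference(ap_f$mean, mp_f$mean)),
      cmp("pullout_ap_of_control_mp", "newton",
          percent_of(ap_f$mean, ctl_f$mean)),
      # labelled explicitly: control-vs-decalcified excess as a percent
      # of the decalcified-MP baseline
      cmp("pullout_control_vs_mp_of_mp", "newton",
          percent_difference(ctl_f$mean, mp_f$mean)))
  }

  structure(list(tprime = tp, comparisons = comparisons),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("T' scores (vs reference population):\n")
  print(x$tprime, row.names = FALSE)
  cat("\nComparisons:\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
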
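# Group-contribution property estimation used to feed the EoS route when no
# experimental critical constants exist (the usual case for drugs).

.gc_table <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "scsolub",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}

.gc_counts <- function(group_counts, table, what) {
  if (length(group_counts) == 0 || sum(group_counts) == 0)
    stop("empty group multiset", call. = FALSE)
  unknown <- setdiff(names(group_counts), table$group)
  if (length(unknown))
    stop(sprintf("group label(s) not tabulated for %s: %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  group_counts
}

#' Joback group-contribution critical properties
#'
#' Standard Joback sums: `Tb = 198.2 + sum(dTb)`,
#' `Tc = Tb / (0.584 + 0.965 S - S^2)` with `S = sum(dTc)`, and
#' `Pc = (0.113 + 0.0032 n_atoms - sum(dPc))^-2` in bar. When no boiling
#' point is supplied the Joback Tb estimate is used. The shipped group table
#' (`joback_groups.csv`) is a partial transcription of the published table
#' covering alkyl, aromatic and the common polar/halogen substituents.
#'
#' @param group_counts named integer vector of group multiplicities, e.g.
#'   `c(CH3 = 2, CH2 = 6)` for n-octane.
#' @param Tb experimental normal boiling point (K), optional.
#' @return list with `Tc` (K), `Pc` (bar), `Tb` (K) and `Tb_estimated`.
#' @examples
#' joback_critical(c(CH3 = 2, CH2 = 6), Tb = 398.8)  # n-octane
#' @export
joback_critical <- function(group_counts, Tb = NULL) {
  tab <- .gc_table("joback_groups.csv")
  group_counts <- .gc_counts(group_counts, tab, "the Joback method")
  i <- match(names(group_counts), tab$group)
  n <- as.numeric(group_counts)
  Tb_est <- is.null(Tb)
  if (Tb_est) Tb <- 198.2 + sum(n * tab$dTb[i])
  S <- sum(n * tab$dTc[i])
  Tc <- Tb / (0.584 + 0.965 * S - S^2)
  n_atoms <- sum(n * tab$n_atoms[i])
  Pc <- (0.113 + 0.0032 * n_atoms - sum(n * tab$dPc[i]))^-2
  list(Tc = Tc, Pc = Pc, Tb = Tb, Tb_estimated = Tb_est)
}

#' Constantinou-Gani acentric factor (first order)
#'
#' `omega = 0.4085 * (log(W + 1.1507))^(1/0.5050)` with `W` the sum of
#' first-order group contributions. The shipped contribution table
#' (`cg_first_order.csv`) is a partial transcription restricted to the
#' alkyl groups whose published values could be sourced verbatim; requests
#' involving other groups error rather than silently extrapolate.
#'
#' @param group_counts named integer vector of first-order group counts.
#' @return the estimated acentric factor.
#' @examples
#' constantinou_gani_omega(c(CH3 = 2, CH2 = 4))  # n-hexane
#' @export
constantinou_gani_omega <- function(group_counts) {
  tab <- .gc_table("cg_first_order.csv")
  group_counts <- .gc_counts(group_counts, tab, "the Constantinou-Gani method")
  i <- match(names(group_counts), tab$group)
  W <- sum(as.numeric(group_counts) * tab$w[i])
  0.4085 * (log(W + 1.1507))^(1 / 0.5050)
}
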
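#' Recompute published quantities from deposited source-data tables
#'
#' Given local copies of the study's deposited tables, re-runs the
#' package's estimators on the real measurements: the stress-elongation
#' regression (slope `K*/K` and intercept `(1 - K*/K) tau R_rr`), the
#' Pearson correlation of area pressure with distance to the center, the
#' relaxation time `tau` (combining the regression with the measured
#' cumulative radial T1 rate), and the radial elongation profile.
#'
#' Expected files under `dir` (CSV; columns are remappable through
#' `schema`):
#' \describe{
#'   \item{`ablation.csv`}{per-ablation table (laser-ablation source data):
#'     columns `Q_proj` (cell elongation projected on the stress axis),
#'     `s_tilde` (normalized stress `sigma~/2K`), `p` (normalized area
#'     pressure), `r` (distance to center, um), `region` (`DV_band` /
#'     `outside`).}
#'   \item{`cumulative_shear.csv`}{cumulative radial shear curves: columns
#'     `time` (hr) and `t1` (cumulative radial T1 contribution).}
#'   \item{`elongation_profile.csv`}{radial elongation table: columns
#'     `bin_r` (um) and `Qrr`.}
#' }
#' These are not redistributed with the package; download them from the
#' journal's source-data files and the Dryad deposition and export the
#' relevant sheets as CSV.
#'
#' @param dir directory holding the CSV exports.
#' @param schema optional named list of per-file column remappings.
#' @return list with `eq7` (slope/intercept fit), `pressure_correlation`,
#'   `tau_hr`, `Rrr_per_hr`, and `qrr_at_40um`.
#' @export
reproduce_from_source_data <- function(dir, schema = list()) {
  rd <- function(name, need) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f))
      stop("source-data file not found: ", f,
           " (deposited data must be downloaded separately)", call. = FALSE)
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    map <- schema[[name]]
    if (!is.null(map))
      for (ours in names(map)) names(df)[names(df) == map[[ours]]] <- ours
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("file ", f, " lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    df
  }
  abl <- rd("ablation", c("Q_proj", "s_tilde", "p", "r", "region"))
  out <- abl[abl$region == "outside", , drop = FALSE]
  eq7 <- fit_eq7(out$Q_proj, out$s_tilde)
  pcor <- stats::cor(out$r, out$p)
  cum <- rd("cumulative_shear", c("time", "t1"))
  # cumulative T1 curve is ~linear after the adaption phase; its slope is
  # the radial rearrangement rate
  Rrr <- unname(stats::coef(stats::lm(t1 ~ time, cum))[2])
  tau <- estimate_tau(eq7$intercept, eq7$slope, Rrr)
  prof <- rd("elongation_profile", c("bin_r", "Qrr"))
  q40 <- prof$Qrr[which.min(abs(prof$bin_r - 40))]
  list(eq7 = eq7, pressure_correlation = pcor, tau_hr = tau,
       Rrr_per_hr = Rrr, qrr_at_40um = q40)
}
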
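# Co-culture competition statistics: CFU arithmetic from serial-dilution
# spotting, the competitive index, reporter fold induction and
# propidium-iodide positive fractions.

#' CFU per mL from a dilution spot
#'
#' `colonies / (dilution * plated_volume_ml)`. Zero colonies return 0 with a
#' detection-limit flag; counts outside the reliable 3-100 band are flagged
#' as unreliable (a QC convention for 10 uL spots).
#'
#' @param colonies Non-negative colony count.
#' @param dilution Dilution factor in (0, 1], e.g. 1e-5.
#' @param plated_volume_ml Plated volume in mL (default 0.01 = 10 uL spots).
#' @return Numeric CFU/mL with attributes `at_detection_limit` and
#'   `reliable`.
#' @export
cfu_per_ml <- function(colonies, dilution, plated_volume_ml = 0.01) {
  stopifnot(colonies >= 0, dilution > 0, dilution <= 1, plated_volume_ml > 0)
  val <- colonies / (dilution * plated_volume_ml)
  attr(val, "at_detection_limit") <- colonies == 0
  attr(val, "reliable") <- colonies >= 3 && colonies <= 100
  val
}

#' Competitive index
#'
#' `ci = (ind_tf / prod_tf) / (ind_t0 / prod_t0)`: the indicator/producer
#' ratio at the final time point normalised by the ratio at t = 0. CI near 1
#' means no differential killing. A zero indicator count at the final time
#' is reported as an upper bound at the detection limit (using 1 colony
#' equivalent supplied via `detection_limit`); a zero producer count is an
#' error.
#'
#' @param ind_t0,prod_t0 CFU/mL of indicator and producer at t = 0 (> 0).
#' @param ind_tf,prod_tf CFU/mL at the final time point.
#' @param detection_limit CFU/mL equivalent of one colony at the lowest
#'   dilution plated; used when `ind_tf` is 0.
#' @return List of class `CompetitionResult`: `ci`, `log10_ci`,
#'   `is_upper_bound`.
#' @export
competitive_index <- function(ind_t0, prod_t0, ind_tf, prod_tf,
                              detection_limit = NULL) {
  stopifnot(ind_t0 > 0, prod_t0 > 0, ind_tf >= 0, prod_tf >= 0)
  if (prod_tf == 0) stop("producer CFU at final time is 0: CI undefined")
  upper <- FALSE
  if (ind_tf == 0) {
    if (is.null(detection_limit)) {
      stop("indicator CFU at final time is 0; supply detection_limit ",
           "to report an upper bound")
    }
    ind_tf <- detection_limit
    upper <- TRUE
  }
  ci <- (ind_tf / prod_tf) / (ind_t0 / prod_t0)
  structure(list(ci = ci, log10_ci = log10(ci), is_upper_bound = upper),
            class = "CompetitionResult")
}

#' Reporter fold induction relative to a baseline culture density
#'
#' Fluorescence density at each OD divided by the value at the baseline OD
#' (default 0.025, early exponential phase).
#'
#' @param od Culture densities (OD600).
#' @param fluorescence Fluorescence density at each OD.
#' @param baseline_od Baseline density (default 0.025).
#' @param tol Tolerance for locating the baseline point.
#' @return Data frame with `od`, `fluorescence`, `fold`.
#' @export
fold_induction <- function(od, fluorescence, baseline_od = 0.025,
                           tol = 1e-6) {
  stopifnot(length(od) == length(fluorescence), all(fluorescence >= 0))
  base_i <- which(abs(od - baseline_od) <= tol)
  if (length(base_i) == 0) {
    stop("no measurement at baseline OD ", baseline_od)
  }
  base <- fluorescence[base_i[1]]
  if (base <= 0) stop("baseline fluorescence is not positive")
  data.frame(od = od, fluorescence = fluorescence, fold = fluorescence / base)
}

#' Propidium-iodide positive fraction across fields of view
#'
#' Per-field fraction, mean and standard deviation. Counting fewer than 3
#' fields or fewer than 250 cells in a field is flagged, not fatal.
#'
#' @param fields Data frame (or matrix) with columns `total` and
#'   `pi_positive`.
#' @return List: `per_field` fractions, `mean`, `sd`, `flags`.
#' @export
pi_fraction <- function(fields) {
  fields <- as.data.frame(fields)
  stopifnot(all(c("total", "pi_positive") %in% names(fields)))
  if (any(fields$pi_positive > fields$total)) {
    stop("pi_positive exceeds total in at least one field")
  }
  stopifnot(all(fields$total > 0))
  flags <- character(0)
  if (nrow(fields) < 3) flags <- c(flags, "fewer than 3 fields")
  if (any(fields$total < 250)) flags <- c(flags, "field with < 250 cells")
  fr <- fields$pi_positive / fields$total
  list(per_field = fr, mean = mean(fr), sd = stats::sd(fr), flags = flags)
}

#' Competitive indices from a CFU observation table
#'
#' Input columns: `strain`, `role` (`indicator`/`producer`), `replicate`,
#' `time_hr`, `dilution`, `colonies`, and optionally `volume_ml`. CFU/mL is
#' computed per row; the CI uses the earliest and latest time point of each
#' replicate.
#'
#' @param obs Observation data frame (e.g. read from TSV).
#' @return Data frame, one row per replicate: `replicate`, `t0`, `tf`, `ci`,
#'   `log10_ci`.
#' @export
competition_table <- function(obs) {
  stopifnot(all(c("role", "replicate", "time_hr", "dilution", "colonies")
                %in% names(obs)))
  if (is.null(obs$volume_ml)) obs$volume_ml <- 0.01
  obs$cfu <- mapply(function(k, d, v) as.numeric(cfu_per_ml(k, d, v)),
                    obs$colonies, obs$dilution, obs$volume_ml)
  out <- lapply(split(obs, obs$replicate), function(d) {
    t0 <- min(d$time_hr); tf <- max(d$time_hr)
    pick <- function(role, t) {
      v <- d$cfu[d$role == role & d$time_hr == t]
      if (length(v) != 1) stop("replicate ", d$replicate[1],
                               ": need exactly one ", role, " row at t=", t)
      v
    }
    r <- competitive_index(pick("indicator", t0), pick("producer", t0),
                           pick("indicator", tf), pick("producer", tf),
                           detection_limit = 1 / (min(d$dilution) * 0.01))
    data.frame(replicate = d$replicate[1], t0 = t0, tf = tf,
               ci = r$ci, log10_ci = r$log10_ci,
               is_upper_bound = r$is_upper_bound)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
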
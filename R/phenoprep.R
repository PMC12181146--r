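#' Preprocessing configuration
#'
#' Holds the constants of the phenotype preparation pipeline: the statin
#' correction divisor for measured LDL-C, the additive SBP correction for
#' antihypertensive users, the winsorization width in SD units, whether TG
#' is natural-log transformed, and which traits the complete-case filter
#' covers.
#'
#' @param statin_ldl_divisor Measured LDL-C of statin users is divided by
#'   this to approximate the untreated value (default 0.7).
#' @param bp_med_sbp_addition mmHg added to the mean SBP of antihypertensive
#'   users (default 10).
#' @param winsor_k Half-width of the winsorization band in SD units
#'   (default 6).
#' @param tg_log Natural-log transform TG before analysis (default TRUE).
#' @param winsorize_after_correction Apply winsorization after the
#'   medication corrections (default) rather than before them.
#' @param complete_case_traits Traits whose joint completeness is required
#'   (default all five).
#' @return A `prep_config` list.
#' @export
prep_config <- function(statin_ldl_divisor = 0.7,
                        bp_med_sbp_addition = 10,
                        winsor_k = 6,
                        tg_log = TRUE,
                        winsorize_after_correction = TRUE,
                        complete_case_traits = sim_traits) {
  if (statin_ldl_divisor <= 0 || statin_ldl_divisor > 1) {
    stop("statin_ldl_divisor must be in (0, 1]", call. = FALSE)
  }
  if (bp_med_sbp_addition < 0) {
    stop("bp_med_sbp_addition must be >= 0", call. = FALSE)
  }
  if (winsor_k <= 0) stop("winsor_k must be > 0", call. = FALSE)
  structure(list(statin_ldl_divisor = statin_ldl_divisor,
                 bp_med_sbp_addition = bp_med_sbp_addition,
                 winsor_k = winsor_k, tg_log = tg_log,
                 winsorize_after_correction = winsorize_after_correction,
                 complete_case_traits = complete_case_traits),
            class = "prep_config")
}

prep_state <- function(table) {
  st <- attr(table, "prep_state")
  if (is.null(st)) "raw" else st
}

mark_state <- function(table, state) {
  attr(table, "prep_state") <- state
  table
}

#' Average duplicate SBP readings
#'
#' When the table carries two SBP readings (`sbp1`, `sbp2`), replaces them
#' by their mean in an `sbp` column; a single `sbp` column passes through.
#'
#' @param table Phenotype data frame.
#' @return Table with a single `sbp` column.
#' @export
average_sbp_readings <- function(table) {
  if (all(c("sbp1", "sbp2") %in% names(table))) {
    table$sbp <- rowMeans(table[, c("sbp1", "sbp2")], na.rm = FALSE)
    table$sbp1 <- NULL
    table$sbp2 <- NULL
  }
  table
}

#' Undo medication masking of measured LDL-C and SBP
#'
#' Statin users' measured LDL-C is divided by the configured divisor
#' (statins reduce LDL-C roughly multiplicatively, so division approximates
#' the untreated level); antihypertensive users get the configured mmHg
#' added to their mean SBP. ApoB and TG are deliberately untouched for
#' statin users. Refuses to run twice on the same table.
#'
#' @param raw Phenotype data frame in the raw state, with `statin` and
#'   `bp_med` 0/1 flags and a single (already averaged) `sbp` column.
#' @param cfg A [prep_config()].
#' @return Corrected table (still raw-scale TG).
#' @export
correct_medications <- function(raw, cfg = prep_config()) {
  if (prep_state(raw) != "raw") {
    stop("state error: medication corrections already applied ",
         "(double correction forbidden)", call. = FALSE)
  }
  stopifnot(all(c("ldl", "sbp", "statin", "bp_med") %in% names(raw)))
  out <- raw
  st <- !is.na(out$statin) & out$statin == 1
  out$ldl[st] <- out$ldl[st] / cfg$statin_ldl_divisor
  bp <- !is.na(out$bp_med) & out$bp_med == 1
  out$sbp[bp] <- out$sbp[bp] + cfg$bp_med_sbp_addition
  mark_state(out, "corrected")
}

#' Natural-log transform triglycerides
#'
#' Replaces the raw mmol/L TG column by its natural logarithm (TG is
#' right-skewed; the log restores approximate normality for the linear
#' models).
#'
#' @param table Phenotype data frame with `tg` on the raw scale.
#' @return Table with `tg` on the log scale and a `tg_scale` attribute.
#' @export
transform_tg <- function(table) {
  if (identical(attr(table, "tg_scale"), "log")) {
    stop("state error: tg already log-transformed", call. = FALSE)
  }
  bad <- which(!is.na(table$tg) & table$tg <= 0)
  if (length(bad) > 0) {
    id <- if ("sample_id" %in% names(table)) {
      table$sample_id[bad[1]]
    } else {
      as.character(bad[1])
    }
    stop("value error: non-positive TG for sample ", id, call. = FALSE)
  }
  table$tg <- log(table$tg)
  attr(table, "tg_scale") <- "log"
  table
}

#' Winsorize a trait vector at k standard deviations
#'
#' Mean and SD are computed once on the non-missing input values; every
#' value outside `[m - k*s, m + k*s]` is set exactly to the nearer bound.
#' Because the bounds come from the pre-clip moments, applying the returned
#' bounds a second time is an exact no-op. Missing values pass through.
#'
#' @param values Numeric vector.
#' @param k Band half-width in SD units (default 6).
#' @return Clipped vector, with the bounds attached as attribute
#'   `winsor_bounds`.
#' @export
winsorize <- function(values, k = 6) {
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values", call. = FALSE)
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (s == 0) {
    warning("zero SD: winsorization is a no-op")
    attr(values, "winsor_bounds") <- c(m, m)
    return(values)
  }
  lo <- m - k * s
  hi <- m + k * s
  out <- pmin(pmax(values, lo), hi)
  out[!ok] <- NA_real_
  attr(out, "winsor_bounds") <- c(lo, hi)
  out
}

#' Remove individuals missing any required trait
#'
#' @param table Phenotype data frame.
#' @param traits Traits whose completeness is required (default all five).
#' @return Filtered table; the number of removed rows is attached as
#'   attribute `n_removed`.
#' @export
complete_case_filter <- function(table, traits = sim_traits) {
  miss <- Reduce(`|`, lapply(traits, function(tr) is.na(table[[tr]])))
  if (is.null(miss)) miss <- rep(FALSE, nrow(table))
  out <- table[!miss, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("empty cohort after complete-case filtering", call. = FALSE)
  }
  attr(out, "n_removed") <- sum(miss)
  attr(out, "prep_state") <- attr(table, "prep_state")
  attr(out, "tg_scale") <- attr(table, "tg_scale")
  rownames(out) <- NULL
  out
}

#' Run the full phenotype preparation pipeline
#'
#' Fixed stage order: average duplicate SBP readings, medication
#' corrections, TG log transform, per-trait winsorization on the analysis
#' scale, complete-case filter. Corrections precede winsorization so the
#' +10 mmHg shift cannot push values past a clip bound computed on the
#' uncorrected data; set `winsorize_after_correction = FALSE` in the config
#' to clip first instead.
#'
#' @param raw Raw phenotype data frame.
#' @param cfg A [prep_config()].
#' @return Preprocessed table (state `"preprocessed"`), with per-stage
#'   counts in attribute `prep_log`.
#' @export
preprocess_phenotypes <- function(raw, cfg = prep_config()) {
  if (prep_state(raw) != "raw") {
    stop("state error: table is not in the raw state", call. = FALSE)
  }
  tab <- average_sbp_readings(raw)
  log <- list(n_input = nrow(tab))

  wins <- function(t) {
    for (tr in sim_traits) {
      if (sum(!is.na(t[[tr]])) >= 2 && stats::sd(t[[tr]], na.rm = TRUE) > 0) {
        t[[tr]] <- as.vector(winsorize(t[[tr]], cfg$winsor_k))
      }
    }
    t
  }

  if (!cfg$winsorize_after_correction) tab <- wins(tab)
  tab <- correct_medications(tab, cfg)
  if (cfg$tg_log) tab <- transform_tg(tab)
  if (cfg$winsorize_after_correction) tab <- wins(tab)
  tab <- complete_case_filter(tab, cfg$complete_case_traits)
  log$n_removed_incomplete <- attr(tab, "n_removed")
  log$n_output <- nrow(tab)
  attr(tab, "prep_log") <- log
  mark_state(tab, "preprocessed")
}

#' Cohort summary by age group
#'
#' Descriptive baseline table: per age bin and overall, n, sex split, mean
#' (SD) for ApoB, LDL-C, SBP and BMI, median \[IQR\] for age and TG (on the
#' raw mmol/L scale; a log-scale TG column is exponentiated back for
#' display), and medication-use percentages. Quantiles use linear
#' interpolation between order statistics (type 7).
#'
#' @param table Phenotype data frame (raw or preprocessed).
#' @param age_bins Data frame with columns `label`, `lo`, `hi`; bins are
#'   closed-open `[lo, hi)` except the last, which is closed. Default
#'   40-49 / 50-59 / 60-70.
#' @return Data frame, one row per bin plus an `overall` row.
#' @export
summarize_cohort <- function(table, age_bins = default_age_bins()) {
  tg_raw <- if (identical(attr(table, "tg_scale"), "log")) {
    exp(table$tg)
  } else {
    table$tg
  }
  bin_of <- assign_age_bins(table$age, age_bins)

  one <- function(idx, label) {
    n <- length(idx)
    if (n == 0) {
      return(data.frame(group = label, n = 0, pct_female = NA_real_,
                        age_median = NA_real_, age_q1 = NA_real_,
                        age_q3 = NA_real_,
                        apob_mean = NA_real_, apob_sd = NA_real_,
                        ldl_mean = NA_real_, ldl_sd = NA_real_,
                        tg_median = NA_real_, tg_q1 = NA_real_,
                        tg_q3 = NA_real_,
                        sbp_mean = NA_real_, sbp_sd = NA_real_,
                        bmi_mean = NA_real_, bmi_sd = NA_real_,
                        statin_pct = NA_real_, bp_med_pct = NA_real_))
    }
    qs <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE,
                                      names = FALSE, type = 7)
    aq <- qs(table$age[idx]); tq <- qs(tg_raw[idx])
    data.frame(
      group = label, n = n,
      pct_female = 100 * mean(table$sex[idx] == "female", na.rm = TRUE),
      age_median = aq[1], age_q1 = aq[2], age_q3 = aq[3],
      apob_mean = mean(table$apob[idx], na.rm = TRUE),
      apob_sd = stats::sd(table$apob[idx], na.rm = TRUE),
      ldl_mean = mean(table$ldl[idx], na.rm = TRUE),
      ldl_sd = stats::sd(table$ldl[idx], na.rm = TRUE),
      tg_median = tq[1], tg_q1 = tq[2], tg_q3 = tq[3],
      sbp_mean = mean(table$sbp[idx], na.rm = TRUE),
      sbp_sd = stats::sd(table$sbp[idx], na.rm = TRUE),
      bmi_mean = mean(table$bmi[idx], na.rm = TRUE),
      bmi_sd = stats::sd(table$bmi[idx], na.rm = TRUE),
      statin_pct = 100 * mean(table$statin[idx], na.rm = TRUE),
      bp_med_pct = 100 * mean(table$bp_med[idx], na.rm = TRUE))
  }
  rows <- lapply(seq_len(nrow(age_bins)), function(b) {
    one(which(bin_of == age_bins$label[b]), age_bins$label[b])
  })
  rows <- c(rows, list(one(which(!is.na(bin_of)), "overall")))
  do.call(rbind, rows)
}

#' Default age bins
#'
#' Closed-open bins `[40, 50)`, `[50, 60)` and closed `[60, 70]`; an age of
#' exactly 70 belongs to the top bin.
#'
#' @return Data frame with `label`, `lo`, `hi`.
#' @export
default_age_bins <- function() {
  data.frame(label = c("40-49", "50-59", "60-70"),
             lo = c(40, 50, 60), hi = c(50, 60, 70),
             stringsAsFactors = FALSE)
}

#' Assign ages to bins
#'
#' @param age Numeric ages.
#' @param age_bins Bin table as in [default_age_bins()].
#' @return Character vector of bin labels (NA outside all bins).
#' @export
assign_age_bins <- function(age, age_bins = default_age_bins()) {
  out <- rep(NA_character_, length(age))
  last <- nrow(age_bins)
  for (b in seq_len(last)) {
    inb <- if (b == last) {
      age >= age_bins$lo[b] & age <= age_bins$hi[b]
    } else {
      age >= age_bins$lo[b] & age < age_bins$hi[b]
    }
    out[which(inb)] <- age_bins$label[b]
  }
  out
}
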
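#' Assay configuration
#'
#' The plasma assay was linear over 2--100 mg/L; `lloq` is the lower limit of
#' quantification and `bloq_policy` what to do with observations below it:
#' drop them (default), impute half the LLOQ, or set them to zero. The source
#' cohort reported no below-LLOQ handling, so "drop" is the default and the
#' alternatives record the ambiguity.
#'
#' @param lloq lower limit of quantification (mg/L).
#' @param bloq_policy one of "drop", "lloq_half", "zero".
#' @return object of class `assay_config`.
#' @export
assay_config <- function(lloq = 2, bloq_policy = c("drop", "lloq_half", "zero")) {
  if (lloq <= 0) stop("lloq must be > 0")
  structure(list(lloq = lloq, bloq_policy = match.arg(bloq_policy)),
            class = "assay_config")
}

.EVENT_COLS <- c("subject_id", "time_h", "evid", "amt_mg", "dur_h",
                 "dv_mg_L", "bloq", "ss", "tau_h")
.COV_COLS <- c("crcl_ml_min", "age_y", "weight_kg", "height_cm", "sex",
               "apache2", "diagnosis", "albumin_g_dl", "glucose_mg_dl",
               "bilirubin_mg_dl", "hemoglobin_g_dl", "leukocytes_1e9_L")
.MANDATORY_COLS <- c("subject_id", "time_h", "evid", "amt_mg", "dur_h",
                     "dv_mg_L", "bloq", "crcl_ml_min")

#' Event-record PK dataset
#'
#' The single interchange container of the pipeline: one row per event (dose
#' or observation) plus a per-subject covariate table. Dose rows (`evid = 1`)
#' carry `amt_mg` and `dur_h` (and optionally `ss`/`tau_h` for steady-state
#' dosing with interval `tau_h`); observation rows (`evid = 0`) carry
#' `dv_mg_L` and a below-LLOQ flag `bloq`. Times are hours since first dose.
#'
#' @param records data.frame of event rows (columns `subject_id`, `time_h`,
#'   `evid`, `amt_mg`, `dur_h`, `dv_mg_L`, `bloq`, optionally `ss`, `tau_h`).
#' @param subjects data.frame with `subject_id` and covariate columns
#'   (`crcl_ml_min`, `age_y`, ...).
#' @param validate run [validate_pk_dataset()].
#' @return object of class `pk_dataset`.
#' @export
pk_dataset <- function(records, subjects, validate = TRUE) {
  records <- as.data.frame(records)
  subjects <- as.data.frame(subjects)
  if (!"ss" %in% names(records)) records$ss <- rep(0L, nrow(records))
  if (!"tau_h" %in% names(records)) records$tau_h <- rep(NA_real_, nrow(records))
  records$ss[is.na(records$ss)] <- 0L
  if (nrow(records)) {
    records <- records[order(records$subject_id, records$time_h, records$evid), , drop = FALSE]
    rownames(records) <- NULL
  }
  d <- structure(list(records = records, subjects = subjects),
                 class = "pk_dataset")
  if (validate) validate_pk_dataset(d)
  d
}

#' Validate a pk_dataset against its invariants
#'
#' Checks: times non-negative and non-decreasing within subject; observation
#' rows have a finite concentration >= 0 or a BLOQ flag; dose rows have
#' amount > 0 and infusion duration > 0; kind-specific fields are mutually
#' exclusive; every subject with observations has at least one dose row;
#' `crcl_ml_min > 0` for every subject.
#'
#' @param d a [pk_dataset()].
#' @return `d`, invisibly; errors are row-addressable.
#' @export
validate_pk_dataset <- function(d) {
  r <- d$records
  s <- d$subjects
  bad <- function(rows, what) {
    stop(sprintf("invalid dataset: %s (row%s %s)", what,
                 if (length(rows) > 1) "s" else "", paste(rows, collapse = ", ")))
  }
  if (nrow(r)) {
    if (any(!is.finite(r$time_h) | r$time_h < 0)) {
      bad(which(!is.finite(r$time_h) | r$time_h < 0), "negative or missing time")
    }
    if (any(!r$evid %in% c(0L, 1L))) bad(which(!r$evid %in% c(0L, 1L)), "evid must be 0 or 1")
    obs <- r$evid == 0L
    dos <- r$evid == 1L
    if (any(dos & (is.na(r$amt_mg) | r$amt_mg <= 0))) {
      bad(which(dos & (is.na(r$amt_mg) | r$amt_mg <= 0)), "dose row with amount <= 0")
    }
    if (any(dos & (is.na(r$dur_h) | r$dur_h <= 0))) {
      bad(which(dos & (is.na(r$dur_h) | r$dur_h <= 0)), "dose row with infusion duration <= 0")
    }
    if (any(dos & !is.na(r$dv_mg_L))) {
      bad(which(dos & !is.na(r$dv_mg_L)), "dose row carrying a concentration")
    }
    if (any(obs & !is.na(r$amt_mg))) {
      bad(which(obs & !is.na(r$amt_mg)), "observation row carrying an amount")
    }
    okdv <- !is.na(r$dv_mg_L) & is.finite(r$dv_mg_L) & r$dv_mg_L >= 0
    if (any(obs & !okdv & !(r$bloq %in% TRUE))) {
      bad(which(obs & !okdv & !(r$bloq %in% TRUE)),
          "observation without a concentration >= 0 or BLOQ flag")
    }
    for (id in unique(r$subject_id)) {
      tt <- r$time_h[r$subject_id == id]
      if (is.unsorted(tt)) stop(sprintf("times not non-decreasing for subject %s", id))
      if (any(r$subject_id == id & obs) && !any(r$subject_id == id & dos)) {
        stop(sprintf("subject %s has observations but no dose record", id))
      }
    }
  }
  if (nrow(s)) {
    if (anyDuplicated(s$subject_id)) stop("duplicate subject ids in covariate table")
    if (any(is.na(s$crcl_ml_min) | s$crcl_ml_min <= 0)) {
      stop(sprintf("crcl_ml_min must be > 0 (subject %s)",
                   s$subject_id[which(is.na(s$crcl_ml_min) | s$crcl_ml_min <= 0)[1]]))
    }
  }
  invisible(d)
}

#' Number of observation rows in a dataset
#' @param d a [pk_dataset()].
#' @export
n_observations <- function(d) sum(d$records$evid == 0L)

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("pk_dataset: %d subjects, %d dose rows, %d observations (%d BLOQ)\n",
              nrow(x$subjects), sum(x$records$evid == 1L), n_observations(x),
              sum(x$records$evid == 0L & x$records$bloq %in% TRUE)))
  invisible(x)
}

# sniff delimiter from the header line
.detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  seps <- c("\t" = lengths(regmatches(hdr, gregexpr("\t", hdr))),
            "," = lengths(regmatches(hdr, gregexpr(",", hdr))),
            ";" = lengths(regmatches(hdr, gregexpr(";", hdr))))
  if (all(seps == 0)) stop("could not detect a delimiter in the header")
  names(seps)[which.max(seps)]
}

#' Read an event-record PK dataset from delimited text
#'
#' Separator (comma, semicolon or tab) is auto-detected from the header.
#' Observations below the LLOQ (or flagged `bloq`) are handled per the assay's
#' BLOQ policy. Rows are sorted by subject then time, and a parse report
#' (doses, observations, BLOQ count) is logged via
#' `options(levipop.verbose = TRUE)`.
#'
#' @param path file path.
#' @param assay an [assay_config()].
#' @return a validated [pk_dataset()].
#' @export
read_dataset <- function(path, assay = assay_config()) {
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.MANDATORY_COLS, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"ss" %in% names(raw)) raw$ss <- rep(0L, nrow(raw))
  if (!"tau_h" %in% names(raw)) raw$tau_h <- rep(NA_real_, nrow(raw))
  raw$bloq <- as.logical(raw$bloq)
  raw$bloq[is.na(raw$bloq)] <- FALSE

  # BLOQ policy
  isobs <- raw$evid == 0L
  below <- isobs & (raw$bloq | (!is.na(raw$dv_mg_L) & raw$dv_mg_L < assay$lloq))
  n_bloq <- sum(below)
  if (n_bloq) {
    if (assay$bloq_policy == "drop") {
      raw <- raw[!below, , drop = FALSE]
    } else if (assay$bloq_policy == "lloq_half") {
      raw$dv_mg_L[below] <- assay$lloq / 2
      raw$bloq[below] <- TRUE
    } else {
      raw$dv_mg_L[below] <- 0
      raw$bloq[below] <- TRUE
    }
  }

  covs_present <- intersect(c("subject_id", .COV_COLS), names(raw))
  subjects <- unique(raw[covs_present])
  rownames(subjects) <- NULL
  records <- raw[intersect(.EVENT_COLS, names(raw))]
  d <- pk_dataset(records, subjects)
  lp_log("read %s: %d subjects, %d doses, %d observations, %d BLOQ (%s)",
         path, nrow(d$subjects), sum(d$records$evid == 1L),
         n_observations(d), n_bloq, assay$bloq_policy)
  d
}

#' Write a pk_dataset to delimited text
#'
#' Covariates are repeated on each event row. Numeric fields are written with
#' 17 significant digits so that `read_dataset(write_dataset(d))` reproduces
#' `d` field-for-field.
#'
#' @param d a [pk_dataset()].
#' @param path output file path; extension `.tsv` writes tab-separated,
#'   anything else comma-separated.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path) {
  covs <- d$subjects
  out <- merge(d$records, covs, by = "subject_id", sort = FALSE)
  out <- out[order(out$subject_id, out$time_h, out$evid), , drop = FALSE]
  cols <- c(intersect(.EVENT_COLS, names(out)), intersect(.COV_COLS, names(out)))
  out <- out[cols]
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  out[out == "NA"] <- NA
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Load a model configuration file
#'
#' Reads a YAML or JSON document whose keys mirror the published final-model
#' table (`theta_nr`, `theta_r`, `v1`, `q`, `v2`, `iiv_cl_pct`, `iiv_v1_pct`,
#' `residual: {kind, sigma_prop_pct, sigma_add}`, and an optional `covariates`
#' list of `{param, cov, form, centre, theta, level}` entries). Any omitted
#' field defaults to the published final model, so an empty document loads the
#' final model itself.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [final_model()]-style `pk_model`.
#' @export
load_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- cfg %||% list()
  num <- function(key, default) {
    v <- cfg[[key]] %||% default
    if (!is.numeric(v) || !is.finite(v)) stop(sprintf("config field '%s' must be numeric", key))
    v
  }
  for (key in c("theta_nr", "v1", "q", "v2")) {
    if (!is.null(cfg[[key]]) && cfg[[key]] <= 0) {
      stop(sprintf("config field '%s' must be positive", key))
    }
  }
  params <- pk_params(theta_nr = num("theta_nr", 3.5),
                      theta_r = num("theta_r", 2.5),
                      v1 = num("v1", 20.7), q = num("q", 31.9),
                      v2 = num("v2", 33.5))
  omega <- omega_spec(cl = num("iiv_cl_pct", 32.7) / 100,
                      v1 = num("iiv_v1_pct", 56.1) / 100)
  rcfg <- cfg$residual %||% list()
  residual <- residual_spec(kind = rcfg$kind %||% "proportional",
                            sigma_prop = (rcfg$sigma_prop_pct %||% 22.3) / 100,
                            sigma_add = rcfg$sigma_add %||% 0)
  covariates <- NULL
  if (!is.null(cfg$covariates)) {
    effs <- lapply(cfg$covariates, function(e) {
      if (!e$form %in% c("power", "linear", "exponential", "shift")) {
        stop(sprintf("unknown covariate function name '%s'", e$form))
      }
      cov_effect(e$param, e$cov, e$form, centre = e$centre %||% NA_real_,
                 theta = e$theta %||% NA_real_, level = e$level)
    })
    covariates <- covariate_model(effs)
  }
  final_model(params = params, omega = omega, residual = residual,
              covariates = covariates)
}
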
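## Subject-level data container and CSV interface.
##
## A dataset is held as two linked tables: one row per subject
## (id, treatment arm, baseline covariates, observed confounder level, exit
## time, event indicator) and a long-format table of mediator measurements
## (id, time in years, value on the analysis scale).  Categorical codings:
## treatment A is 0 (control) / 1 (intervention); the ordinal confounder L
## takes values 0..K-1 with higher = more favourable lifestyle; baseline
## covariates are integer-coded with 0 as the reference level.

W_COLS <- c("age_cat", "sex", "smoking", "base_score")
W_LEVELS <- list(age_cat = 0:2, sex = 0:1, smoking = 0:2, base_score = 0:2)

new_tdc_data <- function(subjects, visits) {
  structure(list(subjects = subjects, visits = visits), class = "tdc_data")
}

#' @export
print.tdc_data <- function(x, ...) {
  cat(sprintf("Mediation dataset: %d subjects (%d intervention, %d control), %d events, %d mediator measurements\n",
              nrow(x$subjects), sum(x$subjects$A == 1), sum(x$subjects$A == 0),
              sum(x$subjects$d), nrow(x$visits)))
  invisible(x)
}

validate_tdc_data <- function(data, K = 3) {
  s <- data$subjects; v <- data$visits
  if (anyDuplicated(s$id)) {
    stop("duplicated subject ids: ",
         paste(unique(s$id[duplicated(s$id)]), collapse = ", "), call. = FALSE)
  }
  if (!all(s$A %in% c(0, 1))) {
    badv <- setdiff(unique(s$A), c(0, 1))
    stop(sprintf("unknown level in column 'A': %s", paste(badv, collapse = ", ")),
         call. = FALSE)
  }
  for (w in W_COLS) {
    bad <- !(s[[w]] %in% W_LEVELS[[w]])
    if (any(bad)) {
      stop(sprintf("unknown level in column '%s': %s", w,
                   paste(unique(s[[w]][bad]), collapse = ", ")), call. = FALSE)
    }
  }
  if (!all(s$L %in% 0:(K - 1))) {
    stop(sprintf("unknown level in column 'L': %s",
                 paste(setdiff(unique(s$L), 0:(K - 1)), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(s$d %in% c(0, 1))) stop("event indicator 'd' must be 0/1", call. = FALSE)
  if (any(s$T_exit < 0)) stop("exit times must be nonnegative", call. = FALSE)
  if (nrow(v)) {
    orphan <- setdiff(unique(v$id), s$id)
    if (length(orphan)) {
      stop("longitudinal measurements for unknown subject id(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
    dup <- duplicated(v[c("id", "t")])
    if (any(dup)) {
      d1 <- v[dup, ][1, ]
      stop(sprintf("duplicated (id, time) pair in longitudinal data: (%s, %g)",
                   d1$id, d1$t), call. = FALSE)
    }
    tex <- s$T_exit[match(v$id, s$id)]
    if (any(v$t < 0 | v$t > tex + 1e-9)) {
      bad <- which(v$t < 0 | v$t > tex + 1e-9)[1]
      stop(sprintf("visit time outside [0, T_exit] for id %s at t = %g",
                   v$id[bad], v$t[bad]), call. = FALSE)
    }
  }
  invisible(data)
}

#' Read a subject table and longitudinal table from CSV
#'
#' Reads the two-table dataset layout: `subjects.csv` with columns
#' `id, A, age_cat, sex, smoking, base_score, L, T_exit, d` and
#' `longitudinal.csv` with columns `id, t, m` (time in years, mediator on
#' the analysis scale). Visits are merged per subject and sorted by time.
#' Rows with missing required fields are dropped with a warning naming
#' them; duplicated (id, time) pairs, unknown categorical levels, and
#' measurements for unknown subjects are errors.
#'
#' @param subject_csv,longitudinal_csv file paths.
#' @param K number of confounder levels used for validation.
#' @return object of class `"tdc_data"` with elements `subjects` and
#'   `visits` (both data.frames; visits sorted by id then time).
#' @export
read_dataset <- function(subject_csv, longitudinal_csv, K = 3) {
  for (f in c(subject_csv, longitudinal_csv)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  subj_cols <- c("id", "A", W_COLS, "L", "T_exit", "d")
  s <- utils::read.csv(subject_csv, stringsAsFactors = FALSE)
  miss <- setdiff(subj_cols, names(s))
  if (length(miss)) {
    stop("subject file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  s <- s[subj_cols]
  s$id <- as.character(s$id)
  incomplete <- !stats::complete.cases(s)
  if (any(incomplete)) {
    warning(sprintf("dropped %d subject row(s) with missing fields (rows: %s)",
                    sum(incomplete),
                    paste(which(incomplete), collapse = ", ")), call. = FALSE)
    s <- s[!incomplete, , drop = FALSE]
  }
  v <- utils::read.csv(longitudinal_csv, stringsAsFactors = FALSE)
  if (nrow(v) == 0) {
    warning("longitudinal file has no measurements; all subjects have zero visits",
            call. = FALSE)
    v <- data.frame(id = character(0), t = numeric(0), m = numeric(0))
  } else {
    missv <- setdiff(c("id", "t", "m"), names(v))
    if (length(missv)) {
      stop("longitudinal file lacks required column(s): ",
           paste(missv, collapse = ", "), call. = FALSE)
    }
    v <- v[c("id", "t", "m")]
    v$id <- as.character(v$id)
    incomplete <- !stats::complete.cases(v)
    if (any(incomplete)) {
      warning(sprintf("dropped %d longitudinal row(s) with missing fields (rows: %s)",
                      sum(incomplete),
                      paste(which(incomplete), collapse = ", ")), call. = FALSE)
      v <- v[!incomplete, , drop = FALSE]
    }
    v <- v[order(match(v$id, s$id), v$t), , drop = FALSE]
    rownames(v) <- NULL
  }
  rownames(s) <- NULL
  data <- new_tdc_data(s, v)
  validate_tdc_data(data, K = K)
  data
}

#' Write a dataset back to the two-table CSV layout
#'
#' Numeric fields are written with 17 significant digits so that a
#' read/write round trip reproduces the values bit for bit.
#'
#' @param data a `tdc_data` object.
#' @param subject_csv,longitudinal_csv output paths.
#' @export
write_dataset <- function(data, subject_csv, longitudinal_csv) {
  stopifnot(inherits(data, "tdc_data"))
  fmt <- function(df) {
    for (j in names(df)) {
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    }
    df
  }
  utils::write.csv(fmt(data$subjects), subject_csv, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fmt(data$visits), longitudinal_csv, row.names = FALSE,
                   quote = FALSE)
  invisible(data)
}

#' Ordinal lifestyle score from standardised components
#'
#' Builds the trichotomous lifestyle score from repeated measurements of
#' its components (e.g. physical activity and dietary intakes): each
#' component is standardised by its baseline mean and standard deviation,
#' the per-subject score is the mean of the standardised values over all
#' available visits and components, and the ordinal level is the number of
#' cutpoints strictly below the score (a score exactly at a cutpoint falls
#' in the lower category).
#'
#' @param components numeric matrix, rows = post-baseline visits, columns =
#'   components; `NA` entries (missed measurements) are ignored.
#' @param baseline_means,baseline_sds numeric vectors, one per component;
#'   all SDs must be positive.
#' @param cutpoints increasing numeric vector of cutpoints on the
#'   standardised scale (tertiles of the baseline score distribution give
#'   two cutpoints and three levels).
#' @return list with `score` (numeric) and `level` (integer in
#'   `0..length(cutpoints)`).
#' @export
#' @examples
#' build_lifestyle_score(matrix(c(5, 6), 2, 1), 4, 1, cutpoints = c(-0.43, 0.43))
build_lifestyle_score <- function(components, baseline_means, baseline_sds,
                                  cutpoints) {
  components <- as.matrix(components)
  nc <- ncol(components)
  stopifnot(length(baseline_means) == nc, length(baseline_sds) == nc,
            all(diff(cutpoints) > 0))
  if (any(baseline_sds <= 0)) {
    stop("baseline SDs must be strictly positive", call. = FALSE)
  }
  if (all(is.na(components))) {
    stop("at least one component measurement is required", call. = FALSE)
  }
  z <- sweep(sweep(components, 2, baseline_means, "-"), 2, baseline_sds, "/")
  score <- mean(z, na.rm = TRUE)
  level <- sum(cutpoints < score)
  list(score = score, level = as.integer(level))
}

#' Baseline-covariate strata and their empirical weights
#'
#' Tabulates the observed unique combinations of the baseline covariates
#' (age category, sex, smoking category, baseline lifestyle score) over
#' both arms pooled (treatment is randomised) and attaches their empirical
#' frequencies, which serve as the stratum weights P_W(w) in the effect
#' assembly.
#'
#' @param data a `tdc_data` object, or a data.frame containing the
#'   covariate columns.
#' @return data.frame of class `"stratum_table"` with the covariate
#'   columns, `n` and `weight`; weights sum to one.
#' @export
build_strata <- function(data) {
  s <- if (inherits(data, "tdc_data")) data$subjects else data
  stopifnot(nrow(s) >= 1, all(W_COLS %in% names(s)))
  agg <- stats::aggregate(list(n = rep(1L, nrow(s))), by = s[W_COLS], FUN = sum)
  agg <- agg[do.call(order, agg[W_COLS]), , drop = FALSE]
  agg$weight <- agg$n / sum(agg$n)
  rownames(agg) <- NULL
  class(agg) <- c("stratum_table", "data.frame")
  agg
}
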
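#' Construct a long-format population-PK dataset
#'
#' The canonical in-memory container is a data frame of class `pk_dataset`
#' in NONMEM-style long format, one row per dose event or observation:
#' `id` (subject), `time` (h), `amt` (mg, dose rows only), `dv` (ug/mL,
#' observation rows only), `evid` (1 = dose, 0 = observation), `mdv`
#' (derived: 1 where `dv` is missing), and the time-constant per-subject
#' covariates `crcl` (mL/min), `alb` (g/dL) and `cyp2c9` (genotype label,
#' one of `"*1/*1"`, `"*1/*3"`, `"*3/*3"`).
#'
#' @param id character or coercible subject identifiers.
#' @param time numeric times in hours (non-decreasing within subject).
#' @param evid 1 for dose rows, 0 for observation rows.
#' @param amt dose amount (mg) on dose rows, `NA` elsewhere.
#' @param dv observed concentration (ug/mL) on observation rows, `NA`
#'   elsewhere.
#' @param crcl,alb,cyp2c9 per-row covariates, constant within subject.
#' @param validate validate the assembled dataset (default `TRUE`).
#' @return A `pk_dataset` data frame.
#' @seealso [read_pk_dataset()], [write_pk_dataset()]
#' @export
pk_dataset <- function(id, time, evid, amt = NA_real_, dv = NA_real_,
                       crcl, alb, cyp2c9, validate = TRUE) {
  n <- max(length(id), length(time), length(evid))
  d <- data.frame(id = rep_len(as.character(id), n),
                  time = rep_len(as.numeric(time), n),
                  evid = rep_len(as.integer(evid), n),
                  amt = rep_len(as.numeric(amt), n),
                  dv = rep_len(as.numeric(dv), n),
                  mdv = rep_len(NA_integer_, n),
                  crcl = rep_len(as.numeric(crcl), n),
                  alb = rep_len(as.numeric(alb), n),
                  cyp2c9 = rep_len(as.character(cyp2c9), n),
                  stringsAsFactors = FALSE)
  d$mdv <- ifelse(is.na(d$dv), 1L, 0L)
  class(d) <- c("pk_dataset", "data.frame")
  if (validate) validate_pk_dataset(d)
  d
}

.genotype_levels <- c("*1/*1", "*1/*3", "*3/*3")

#' Validate a population-PK dataset
#'
#' Checks the container invariants: mandatory columns, non-negative
#' non-decreasing times within subject, `dv` present iff observation row,
#' `amt` present iff dose row (under `strict`), positive covariates with
#' known genotype labels constant within subject, and (when `require_obs`)
#' at least one dose and one observation per subject.
#'
#' @param x a `pk_dataset` (or plain data frame with the same columns).
#' @param strict reject `dv` on dose rows and missing/extra `amt` (default
#'   `TRUE`).
#' @param require_obs require every subject to carry at least one
#'   observation, as estimation needs (default `TRUE`); simulation designs
#'   may set this to `FALSE` only for `dv`, never for dose events.
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_pk_dataset <- function(x, strict = TRUE, require_obs = TRUE) {
  need <- c("id", "time", "evid", "amt", "dv", "crcl", "alb", "cyp2c9")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("pk_dataset format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0) stop("pk_dataset validation error at row ", i[1], ": ", what)
  }
  bad_row(!x$evid %in% c(0L, 1L), "evid must be 0 (observation) or 1 (dose)")
  bad_row(is.na(x$time) | x$time < 0, "negative or missing time")
  bad_row(x$evid == 1L & (is.na(x$amt) | x$amt < 0), "dose row without a non-negative amt")
  bad_row(x$evid == 0L & is.na(x$dv), "observation row without dv")
  if (strict) {
    bad_row(x$evid == 1L & !is.na(x$dv), "dv filled on a dose row")
    bad_row(x$evid == 0L & !is.na(x$amt), "amt filled on an observation row")
  }
  bad_row(is.na(x$crcl) | x$crcl <= 0, "crcl must be > 0")
  bad_row(is.na(x$alb) | x$alb <= 0, "albumin must be > 0")
  bad_row(!x$cyp2c9 %in% .genotype_levels,
          paste0("unknown genotype label (expected ",
                 paste(.genotype_levels, collapse = ", "), ")"))
  for (s in split(seq_len(nrow(x)), x$id)) {
    xi <- x[s, ]
    if (is.unsorted(xi$time)) {
      stop("pk_dataset validation error: times not non-decreasing for subject ", xi$id[1])
    }
    if (!any(xi$evid == 1L)) {
      stop("pk_dataset validation error: subject ", xi$id[1], " has no dose event")
    }
    if (require_obs && !any(xi$evid == 0L)) {
      stop("pk_dataset validation error: subject ", xi$id[1], " has no observation")
    }
    if (length(unique(xi$crcl)) > 1 || length(unique(xi$alb)) > 1 ||
        length(unique(xi$cyp2c9)) > 1) {
      stop("pk_dataset validation error: covariates vary over time for subject ", xi$id[1])
    }
  }
  invisible(x)
}

#' Read a NONMEM-style population-PK CSV file
#'
#' Expects a comma-separated file with "." decimals and a header containing
#' (case-insensitively) `ID, TIME, AMT, DV, EVID, CRCL, ALB, CYP2C9`; an
#' `MDV` column is optional and rederived from `DV`. Empty fields and `.`
#' are read as missing.
#'
#' @param path file path.
#' @param strict passed to [validate_pk_dataset()].
#' @return A validated [pk_dataset()] with row order preserved.
#' @export
read_pk_dataset <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", "", "."))
  names(raw) <- tolower(names(raw))
  need <- c("id", "time", "amt", "dv", "evid", "crcl", "alb", "cyp2c9")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("pk_dataset format error: missing column(s) ",
         paste(toupper(miss), collapse = ", "), " in ", path)
  }
  d <- pk_dataset(id = raw$id, time = raw$time, evid = raw$evid,
                  amt = raw$amt, dv = raw$dv, crcl = raw$crcl,
                  alb = raw$alb, cyp2c9 = raw$cyp2c9, validate = FALSE)
  validate_pk_dataset(d, strict = strict)
  d
}

#' Write a population-PK dataset as CSV
#'
#' Writes the same dialect [read_pk_dataset()] accepts (upper-case header,
#' missing numeric fields empty), so that a read/write round trip preserves
#' the numeric content to full precision.
#'
#' @param dataset a `pk_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(dataset, path) {
  out <- data.frame(ID = dataset$id,
                    TIME = format(dataset$time, digits = 17, trim = TRUE, scientific = FALSE),
                    EVID = dataset$evid,
                    AMT = ifelse(is.na(dataset$amt), "",
                                 format(dataset$amt, digits = 17, trim = TRUE, scientific = FALSE)),
                    DV = ifelse(is.na(dataset$dv), "",
                                format(dataset$dv, digits = 17, trim = TRUE, scientific = FALSE)),
                    MDV = dataset$mdv,
                    CRCL = format(dataset$crcl, digits = 17, trim = TRUE, scientific = FALSE),
                    ALB = format(dataset$alb, digits = 17, trim = TRUE, scientific = FALSE),
                    CYP2C9 = dataset$cyp2c9,
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a configuration file (JSON or YAML)
#'
#' JSON is read with jsonlite; `.yml`/`.yaml` files need the optional yaml
#' package.
#'
#' @param path file path ending in `.json`, `.yml` or `.yaml`.
#' @return The parsed configuration as a list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
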
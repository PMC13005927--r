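#' @import data.table
#' @importFrom stats median quantile rbinom rnorm rpois runif setNames
#'   pchisq pnorm pt qlogis plogis integrate sd
#' @importFrom utils head
NULL

# Recognized code systems. Anything else is coerced to OTHER on read.
CODE_TYPES <- c("ICD9", "ICD10", "CPT", "LOINC", "HCPCS", "REVENUE",
                "LOCAL", "OTHER")

#' Construct an event table
#'
#' A longitudinal table of coded events for one healthcare system (site):
#' one row per code endorsement, with the patient it was recorded on, the
#' calendar day, the code itself and its code system.
#'
#' @param site_id Site label.
#' @param patient_id Character vector of patient identifiers.
#' @param date `Date` vector (calendar days; no time of day).
#' @param code Non-empty character vector of code strings.
#' @param code_type Code system per event; one of `"ICD9"`, `"ICD10"`,
#'   `"CPT"`, `"LOINC"`, `"HCPCS"`, `"REVENUE"`, `"LOCAL"`, `"OTHER"`.
#' @return An `event_table`: a `data.table` with columns `patient_id`,
#'   `date`, `code`, `code_type` and attribute `site_id`.
#' @export
event_table <- function(site_id, patient_id, date, code, code_type) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  date <- as.Date(date)
  if (anyNA(date)) stop("event dates must be valid calendar days")
  code <- as.character(code)
  if (any(!nzchar(code))) stop("codes must be non-empty strings")
  code_type <- as.character(code_type)
  bad <- !code_type %in% CODE_TYPES
  if (any(bad)) stop("unknown code_type: ", paste(unique(code_type[bad]), collapse = ", "))
  ev <- data.table(patient_id = as.character(patient_id),
                   date = date, code = code, code_type = code_type)
  setattr(ev, "site_id", site_id)
  setattr(ev, "class", c("event_table", class(ev)))
  ev[]
}

#' Read coded events from a delimited file
#'
#' Expects comma-delimited UTF-8 text with a header containing at least
#' `patient_id`, `date`, `code`, `code_type`; dates are ISO-8601 days.
#' Unrecognized code systems are kept but coerced to `OTHER` with a warning.
#'
#' @param path Path to the events file.
#' @param site_id Site label to attach to the table.
#' @return An [event_table()].
#' @export
read_events <- function(path, site_id) {
  dt <- fread(path, colClasses = list(character = c("patient_id", "code", "code_type")))
  need <- c("patient_id", "date", "code", "code_type")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("events file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  d <- as.Date(as.character(dt$date), format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("unparseable date(s) in ", path, " at line(s): ",
         paste(head(which(is.na(d)) + 1L, 20L), collapse = ", "))
  }
  unk <- !dt$code_type %in% CODE_TYPES
  if (any(unk)) {
    warning("coercing ", sum(unk), " event(s) with unrecognized code_type (",
            paste(unique(dt$code_type[unk]), collapse = ", "), ") to OTHER")
    dt[unk, code_type := "OTHER"]
  }
  event_table(site_id, dt$patient_id, d, dt$code, dt$code_type)
}

#' Write an event table to CSV
#'
#' Canonical round-trip companion to [read_events()]: comma-delimited UTF-8
#' with header and ISO-8601 dates.
#'
#' @param events An [event_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- as.data.table(events)[, .(patient_id, date = format(date, "%Y-%m-%d"),
                                   code, code_type)]
  fwrite(out, path)
  invisible(path)
}

#' Construct a covariate table
#'
#' One row per patient with follow-up person-time (years) and the baseline
#' characteristics used for adjustment throughout: age, sex, insulin use and
#' Elixhauser comorbidity score. Complete data are required; rows with
#' missing values are rejected rather than imputed.
#'
#' @param patient_id Unique patient identifiers.
#' @param person_time Positive follow-up time in years.
#' @param age Age in years.
#' @param sex Binary (0/1).
#' @param insulin_use Binary (0/1).
#' @param elixhauser Non-negative integer comorbidity score.
#' @return A `covariate_table` (`data.table`, keyed by `patient_id`).
#' @export
covariate_table <- function(patient_id, person_time, age, sex, insulin_use,
                            elixhauser) {
  cv <- data.table(patient_id = as.character(patient_id),
                   person_time = as.numeric(person_time),
                   age = as.numeric(age), sex = as.numeric(sex),
                   insulin_use = as.numeric(insulin_use),
                   elixhauser = as.numeric(elixhauser))
  if (anyDuplicated(cv$patient_id)) stop("duplicate patient_id in covariate table")
  if (anyNA(cv)) stop("missing covariate values are not allowed")
  if (any(cv$person_time <= 0)) stop("person_time must be > 0")
  if (any(cv$elixhauser < 0)) stop("elixhauser must be non-negative")
  setkey(cv, patient_id)
  setattr(cv, "class", c("covariate_table", class(cv)))
  cv[]
}

#' Read a covariate table from CSV
#'
#' @param path CSV with header `patient_id, person_time, age, sex,
#'   insulin_use, elixhauser`.
#' @return A [covariate_table()].
#' @export
read_covariates <- function(path) {
  dt <- fread(path, colClasses = list(character = "patient_id"))
  need <- c("patient_id", "person_time", "age", "sex", "insulin_use", "elixhauser")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("covariate file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  covariate_table(dt$patient_id, dt$person_time, dt$age, dt$sex,
                  dt$insulin_use, dt$elixhauser)
}

#' Write a covariate table to CSV
#' @param covars A [covariate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covars, path) {
  fwrite(as.data.table(covars), path)
  invisible(path)
}

#' Build a code-group catalog
#'
#' Maps codes to coarser clinical categories (phecode-style groups for ICD
#' diagnoses, CCS-style groups for procedures). Each code belongs to at most
#' one group; ungrouped codes look up as `"ungrouped"`.
#'
#' @param code Character vector of codes.
#' @param group_id Character vector of group labels, one per code.
#' @return A `group_catalog` with `$code2group` (named character vector) and
#'   `$members` (named list group -> member codes).
#' @export
group_catalog <- function(code = character(), group_id = character()) {
  code <- as.character(code); group_id <- as.character(group_id)
  stopifnot(length(code) == length(group_id))
  dup <- duplicated(code)
  if (any(dup)) {
    conf <- tapply(group_id, code, function(g) length(unique(g)) > 1L)
    if (any(conf))
      stop("code(s) assigned to conflicting groups: ",
           paste(names(conf)[conf], collapse = ", "))
    code <- code[!dup]; group_id <- group_id[!dup]
  }
  structure(list(code2group = setNames(group_id, code),
                 members = split(code, group_id)),
            class = "group_catalog")
}

#' Read a code-group catalog from CSV
#' @param path CSV with header `code, group_id`.
#' @return A [group_catalog()].
#' @export
read_code_groups <- function(path) {
  dt <- fread(path, colClasses = "character")
  if (nrow(dt) == 0L) return(group_catalog())
  miss <- setdiff(c("code", "group_id"), names(dt))
  if (length(miss))
    stop("group file ", path, " is missing column(s): ", paste(miss, collapse = ", "))
  group_catalog(dt$code, dt$group_id)
}

#' Look up the group of one or more codes
#' @param catalog A [group_catalog()].
#' @param codes Character vector.
#' @return Character vector of group labels, `"ungrouped"` where unknown.
#' @export
group_of <- function(catalog, codes) {
  g <- unname(catalog$code2group[codes])
  g[is.na(g)] <- "ungrouped"
  g
}

#' Summarize per-code endorsement frequencies and rates for one site
#'
#' Frequency is the total number of endorsements of a code across all
#' patients and the rate divides by the site's total person-time; patients
#' with no events still contribute their person-time to the denominator.
#' Every event row counts (repeat endorsements on the same day are not
#' deduplicated).
#'
#' @param events An [event_table()].
#' @param covars The companion [covariate_table()]; must cover every patient
#'   appearing in `events`.
#' @return A `frequency_table`: `data.table(code, code_type, frequency,
#'   person_time, rate)` with attribute `site_id`.
#' @export
summarize_frequencies <- function(events, covars) {
  absent <- setdiff(unique(events$patient_id), covars$patient_id)
  if (length(absent))
    stop("event patient(s) absent from covariate table: ",
         paste(head(absent, 5L), collapse = ", "))
  pt <- sum(covars$person_time)
  ft <- as.data.table(events)[, .(frequency = .N,
                                  code_type = code_type[1L]), by = code]
  ft[, `:=`(person_time = pt, rate = frequency / pt)]
  setorder(ft, code)
  setcolorder(ft, c("code", "code_type", "frequency", "person_time", "rate"))
  setattr(ft, "site_id", attr(events, "site_id"))
  setattr(ft, "class", c("frequency_table", class(ft)))
  ft[]
}

#' Non-rare vocabulary of a site
#'
#' Codes endorsed at least `min_freq` times (default 10), the working
#' vocabulary for embeddings and mapping.
#'
#' @param freq A `frequency_table` from [summarize_frequencies()].
#' @param min_freq Minimum endorsement count.
#' @return Sorted character vector of codes.
#' @export
nonrare_vocab <- function(freq, min_freq = 10L) {
  sort(freq$code[freq$frequency >= min_freq])
}

#' Patient-by-code feature matrix
#'
#' Tabulates endorsements of each vocabulary code per patient and applies an
#' elementwise transform: raw `count`, `rate` (count divided by the
#' patient's person-time), `log1p_count`, or `binary` endorsement. Codes
#' outside `vocab` are ignored; all covariate-table patients appear as rows
#' (zero rows for patients without events).
#'
#' @param events An [event_table()].
#' @param covars The companion [covariate_table()].
#' @param vocab Non-empty character vector of codes (column order).
#' @param transform One of `"count"`, `"rate"`, `"log1p_count"`, `"binary"`.
#' @return A `code_matrix`: numeric matrix patients x vocab with
#'   `dimnames`, plus attribute `transform`.
#' @export
patient_code_matrix <- function(events, covars, vocab,
                                transform = c("count", "rate", "log1p_count", "binary")) {
  transform <- match.arg(transform)
  if (length(vocab) == 0L) stop("vocab must be non-empty")
  pats <- covars$patient_id
  absent <- setdiff(unique(events$patient_id), pats)
  if (length(absent))
    stop("event patient(s) absent from covariate table: ",
         paste(head(absent, 5L), collapse = ", "))
  keep <- events$code %in% vocab
  i <- match(events$patient_id[keep], pats)
  j <- match(events$code[keep], vocab)
  X <- matrix(0, nrow = length(pats), ncol = length(vocab),
              dimnames = list(pats, vocab))
  if (length(i)) {
    S <- sparseMatrix(i = i, j = j, x = 1,
                      dims = c(length(pats), length(vocab)))
    X <- as.matrix(S)
    dimnames(X) <- list(pats, vocab)
  }
  X <- switch(transform,
              count = X,
              rate = X / covars$person_time,
              log1p_count = log1p(X),
              binary = (X > 0) + 0)
  attr(X, "transform") <- transform
  class(X) <- c("code_matrix", class(X))
  X
}
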
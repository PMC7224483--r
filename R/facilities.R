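count_columns <- c("mds", "surgeons", "surgical_officers", "anesthesia_mds",
                   "anesthetic_officers", "nurses", "ors", "cases_total",
                   "cases_general_surgery", "cases_ob", "cases_ent")
price_columns <- paste0("cost_", procedure_levels)

unknown_sentinels <- c("", "-", "—") # blank, hyphen, em-dash

#' Path to a packaged data file
#' @param file file name under the package's `extdata` directory; empty
#'   lists the available files.
#' @export
cashdose_extdata <- function(file = "") {
  system.file("extdata", file, package = "cashdose", mustWork = file != "")
}

#' Load the hospital survey table
#'
#' Reads the nine-hospital facility survey (workforce counts, operating
#' rooms, last-month case volumes and the prices of four index procedures
#' in GNF). In the survey, an em-dash (or hyphen, or empty cell) means the
#' value was unknown to the respondent, and the string `NA` in a price
#' column means the hospital does not offer that operation; a price of 0 is
#' a valid (free) price. Unknown cells become `NA` values flagged as
#' imputable; not-offered prices are excluded from all price statistics and
#' are never imputed.
#'
#' @param path CSV file; defaults to the packaged survey table.
#' @return a `hospital_records` data.frame of nine rows with attributes
#'   `price_known` and `offered` (hospital x procedure logical matrices)
#'   and `imputed` (FALSE until [impute_missing()] is applied).
#' @export
load_hospitals <- function(path = cashdose_extdata("hospitals.csv")) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0), strip.white = TRUE)
  needed <- c("hospital_id", count_columns, price_columns)
  if (!all(needed %in% names(raw)))
    stop_config("hospital table is missing columns: ",
                paste(setdiff(needed, names(raw)), collapse = ", "))
  parse_cell <- function(cell, col, row, allow_na) {
    if (cell %in% unknown_sentinels) return(NA_real_)
    if (identical(cell, "NA")) {
      if (allow_na) return(-Inf) # marker: not offered
      stop("malformed value 'NA' in count column '", col, "', row ", row)
    }
    v <- suppressWarnings(as.numeric(gsub(",", "", cell)))
    if (is.na(v) || v < 0)
      stop("malformed value '", cell, "' in column '", col, "', row ", row)
    v
  }
  out <- data.frame(hospital_id = raw$hospital_id)
  for (col in c(count_columns, price_columns)) {
    allow_na <- col %in% price_columns
    out[[col]] <- vapply(seq_len(nrow(raw)), function(i)
      parse_cell(raw[[col]][i], col, raw$hospital_id[i], allow_na), 0)
  }
  offered <- sapply(price_columns, function(col) out[[col]] != -Inf | is.na(out[[col]]))
  known <- sapply(price_columns, function(col) is.finite(out[[col]]))
  for (col in price_columns) out[[col]][out[[col]] == -Inf] <- NA_real_
  dimnames(offered) <- dimnames(known) <-
    list(out$hospital_id, procedure_levels)
  structure(out, price_known = known, offered = offered, imputed = FALSE,
            class = c("hospital_records", "data.frame"))
}

#' Impute unknown survey values by column means
#'
#' Every unknown numeric value is replaced by the arithmetic mean of its
#' column's known values (imputation "using averages for each domain").
#' For price columns the mean is taken over known offered prices, zeros
#' included; not-offered entries remain excluded and are never filled.
#' Known values are unchanged, so each column's mean over originally-known
#' entries is preserved.
#'
#' @param records a `hospital_records` data.frame.
#' @return the records with all unknowns filled and `imputed = TRUE`.
#' @export
impute_missing <- function(records) {
  stopifnot(inherits(records, "hospital_records"))
  offered <- attr(records, "offered")
  for (col in c(count_columns, price_columns)) {
    v <- records[[col]]
    fillable <- if (col %in% price_columns) {
      is.na(v) & offered[, sub("^cost_", "", col)]
    } else is.na(v)
    if (!any(fillable)) next
    known <- v[!is.na(v)]
    if (length(known) == 0)
      stop("column '", col, "' has no known values to impute from")
    records[[col]][fillable] <- mean(known)
  }
  attr(records, "imputed") <- TRUE
  records
}

#' Hospital quality scores
#'
#' Each quality domain (the staffing, operating-room and case-volume
#' columns; prices are excluded because price enters the utility
#' separately) is standardized from 0 to 1 against the best-performing
#' hospital in that domain, `x / max(x)`; a hospital's quality score Q is
#' the unweighted mean of its per-domain scores. A domain whose maximum is
#' 0 carries no ranking information and is dropped with a warning.
#'
#' @param records imputed `hospital_records`.
#' @param domains character vector of domain columns.
#' @return data.frame `hospital_id, Q` with the per-domain score matrix as
#'   attribute `domain_scores`.
#' @export
quality_scores <- function(records, domains = count_columns) {
  stopifnot(inherits(records, "data.frame"), all(domains %in% names(records)))
  m <- as.matrix(records[domains])
  if (anyNA(m))
    stop("quality scoring requires imputed records (no unknown values)")
  maxes <- apply(m, 2, max)
  if (any(maxes == 0)) {
    warning("dropping all-zero quality domain(s): ",
            paste(domains[maxes == 0], collapse = ", "))
    m <- m[, maxes > 0, drop = FALSE]
    maxes <- maxes[maxes > 0]
  }
  scores <- sweep(m, 2, maxes, "/")
  structure(data.frame(hospital_id = records$hospital_id,
                       Q = rowMeans(scores)),
            domain_scores = scores)
}

#' Per-procedure price faced by patients at each hospital
#'
#' Known prices are returned as-is (0 is a valid free price); unknown
#' prices are the column mean of that procedure's known prices; hospitals
#' not offering the procedure get `NA` and are excluded from the choice set
#' of agents needing it.
#'
#' @param records `hospital_records`, raw or imputed.
#' @param procedure one of `procedure_levels`.
#' @return named numeric vector of GNF prices, `NA` = not offered.
#' @export
procedure_price <- function(records, procedure) {
  procedure <- match.arg(procedure, procedure_levels)
  if (!isTRUE(attr(records, "imputed"))) records <- impute_missing(records)
  p <- records[[paste0("cost_", procedure)]]
  names(p) <- records$hospital_id
  p
}

#' Summary statistics of the surveyed surgical prices
#'
#' Price statistics use only entries actually reported by hospitals
#' (imputed values are bookkeeping for the choice model, not data), and
#' not-offered procedures are excluded entirely. Reported integers follow
#' the survey write-up's per-statistic rounding: the cesarean mean is
#' truncated toward zero and the non-cesarean mean is rounded half away
#' from zero.
#'
#' @param records `hospital_records` (knownness is tracked through
#'   imputation, so raw or imputed records give identical results).
#' @return a list with pooled/cesarean/non-cesarean statistics, each raw
#'   and as the `reported` integer vector.
#' @export
cost_summary <- function(records) {
  stopifnot(inherits(records, "hospital_records"))
  known <- attr(records, "price_known")
  vals <- lapply(procedure_levels, function(pr)
    records[[paste0("cost_", pr)]][known[, pr]])
  names(vals) <- procedure_levels
  pooled <- unlist(vals, use.names = FALSE)
  ces <- vals$cesarean
  nonces <- unlist(vals[setdiff(procedure_levels, "cesarean")],
                   use.names = FALSE)
  round_half_up <- function(x) floor(x + 0.5)
  list(
    n_known = length(pooled),
    pooled_mean = mean(pooled),
    cesarean_n = length(ces), cesarean_mean = mean(ces),
    noncesarean_n = length(nonces),
    noncesarean_mean = mean(nonces),
    noncesarean_median = median(nonces),
    noncesarean_min = min(nonces), noncesarean_max = max(nonces),
    max_price = max(pooled),
    reported = c(pooled_mean = round_half_up(mean(pooled)),
                 cesarean_mean = trunc(mean(ces)),
                 noncesarean_mean = round_half_up(mean(nonces)),
                 noncesarean_median = round_half_up(median(nonces)),
                 noncesarean_min = min(nonces),
                 noncesarean_max = max(nonces)))
}

#' Attach planar coordinates to hospital records
#'
#' The survey's GPS coordinates are not public; by default the packaged
#' synthetic placement is used (fixed km coordinates on the 60x60 km plane,
#' the majority near the dense peninsula cluster), keeping runs
#' reproducible. Alternatively coordinates can be drawn from a
#' [density_model()].
#'
#' @param records `hospital_records`.
#' @param coords either a data.frame `hospital_id, x_km, y_km` (default:
#'   the packaged synthetic placement) or a `density_model` to sample from.
#' @return records with `x` and `y` columns, km.
#' @export
place_hospitals <- function(records,
                            coords = utils::read.csv(
                              cashdose_extdata("hospital_locations_synthetic.csv"))) {
  if (inherits(coords, "density_model")) {
    xy <- place_agents(nrow(records), coords)
    records$x <- xy[, "x"]; records$y <- xy[, "y"]
    return(records)
  }
  stopifnot(all(c("hospital_id", "x_km", "y_km") %in% names(coords)))
  i <- match(records$hospital_id, coords$hospital_id)
  if (anyNA(i)) stop_config("coordinates missing for some hospitals")
  records$x <- coords$x_km[i]
  records$y <- coords$y_km[i]
  records
}

#' Assemble the facility model used by the simulation engine
#'
#' Loads, imputes, scores and places the hospitals, returning everything
#' the choice model needs: coordinates, quality scores and the
#' hospital-by-procedure price matrix (`NA` = not offered).
#'
#' @param path hospital survey CSV.
#' @param coords see [place_hospitals()].
#' @return a `facility_model` list with `records`, `Q`, `prices`, `coords`,
#'   `offered`.
#' @export
facility_model <- function(path = cashdose_extdata("hospitals.csv"),
                           coords = NULL) {
  rec <- impute_missing(load_hospitals(path))
  rec <- if (is.null(coords)) place_hospitals(rec) else place_hospitals(rec, coords)
  q <- quality_scores(rec)
  prices <- sapply(procedure_levels, function(pr) procedure_price(rec, pr))
  rownames(prices) <- rec$hospital_id
  structure(list(records = rec, Q = setNames(q$Q, q$hospital_id),
                 prices = prices, offered = attr(rec, "offered"),
                 coords = cbind(x = rec$x, y = rec$y)),
            class = "facility_model")
}

#' Largest price a patient can face across the facility model
#' @param fac a [facility_model()].
#' @export
max_facility_price <- function(fac) max(fac$prices, na.rm = TRUE)
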
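# Occurrence cleaning: record-quality filters and one-per-cell thinning.

#' Default occurrence filter rules
#'
#' Records are retained when they (i) carry coordinates within valid
#' ranges, (ii) have a coordinate uncertainty of at most 10 km or a
#' missing uncertainty value, (iii) have a whitelisted basis of record,
#' and (iv) were collected within the study period (2000--2024). A record
#' with a missing year fails the year filter (conservative: unlike the
#' uncertainty rule, no "missing allowed" exception applies to years).
#'
#' @param maxUncertaintyM Maximum coordinate uncertainty in metres.
#' @param basisWhitelist Accepted basisOfRecord tokens.
#' @param yearRange Inclusive collection-year interval.
#' @return A list of class \code{"occurrenceFilterRules"}.
#' @export
occurrenceFilterRules <- function(
    maxUncertaintyM = 10000,
    basisWhitelist = c("HUMAN_OBSERVATION", "OBSERVATION",
                       "PRESERVED_SPECIMEN", "MACHINE_OBSERVATION"),
    yearRange = c(2000, 2024)) {
  structure(list(maxUncertaintyM = maxUncertaintyM,
                 basisWhitelist = basisWhitelist,
                 yearRange = yearRange),
            class = "occurrenceFilterRules")
}

#' Apply record-quality filters to a raw occurrence table
#'
#' Order-preserving and idempotent; each stage's kept/rejected counts are
#' logged in the result's provenance table.
#'
#' @param raw Data frame with (at least) decimalLongitude and
#'   decimalLatitude; year, coordinateUncertaintyInMeters and
#'   basisOfRecord may be absent, in which case the corresponding filter
#'   treats every value as missing.
#' @param rules A \code{\link{occurrenceFilterRules}} list.
#' @return An \linkS4class{OccurrenceSet}.
#' @export
filterRecords <- function(raw, rules = occurrenceFilterRules()) {
  if (!all(c("decimalLongitude", "decimalLatitude") %in% names(raw)))
    .stopf("occurrence table lacks decimalLongitude/decimalLatitude columns")
  raw <- as.data.frame(raw)
  prov <- data.frame(stage = character(), kept = integer(),
                     rejected = integer(), stringsAsFactors = FALSE)
  note <- function(stage, keep, df) {
    prov <<- rbind(prov, data.frame(stage = stage, kept = sum(keep),
                                    rejected = sum(!keep)))
    df[keep, , drop = FALSE]
  }
  lon <- raw$decimalLongitude; lat <- raw$decimalLatitude
  keep <- is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  df <- note("coordinates", keep, raw)

  unc <- if ("coordinateUncertaintyInMeters" %in% names(df))
    df$coordinateUncertaintyInMeters else rep(NA_real_, nrow(df))
  keep <- is.na(unc) | unc <= rules$maxUncertaintyM
  df <- note("uncertainty", keep, df)

  basis <- if ("basisOfRecord" %in% names(df))
    df$basisOfRecord else rep(NA_character_, nrow(df))
  keep <- !is.na(basis) & basis %in% rules$basisWhitelist
  df <- note("basisOfRecord", keep, df)

  yr <- if ("year" %in% names(df)) df$year else rep(NA_integer_, nrow(df))
  keep <- !is.na(yr) & yr >= rules$yearRange[1] & yr <= rules$yearRange[2]
  df <- note("year", keep, df)

  rownames(df) <- NULL
  new("OccurrenceSet", records = df, provenance = prov)
}

#' @export
setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %d records\n", nrow(object@records)))
  if (nrow(object@provenance)) {
    cat("provenance:\n")
    print(object@provenance, row.names = FALSE)
  }
})

#' Number of records in an occurrence set
#' @param x An \linkS4class{OccurrenceSet}.
#' @export
setMethod("length", "OccurrenceSet", function(x) nrow(x@records))

#' Occurrence records accessor
#' @param occ An \linkS4class{OccurrenceSet}.
#' @return The records data frame.
#' @export
occurrenceRecords <- function(occ) occ@records

#' Thin occurrences to one record per grid cell
#'
#' Retains the first record (in input order) of each occupied cell of the
#' supplied grid, so occurrence cells and model cells coincide. Records
#' falling outside the grid are dropped and logged. Deterministic: no RNG.
#'
#' @param occ An \linkS4class{OccurrenceSet} (or plain data frame).
#' @param grid The \linkS4class{GridSpec} the analysis runs on.
#' @return A thinned \linkS4class{OccurrenceSet} whose records carry a
#'   \code{cell} column of linear cell indices.
#' @export
thinToGrid <- function(occ, grid) {
  if (is.data.frame(occ))
    occ <- new("OccurrenceSet", records = occ,
               provenance = data.frame(stage = character(), kept = integer(),
                                       rejected = integer()))
  df <- occ@records
  cell <- cellFromLonLat(grid, df$decimalLongitude, df$decimalLatitude)
  inGrid <- !is.na(cell)
  prov <- rbind(occ@provenance,
                data.frame(stage = "withinGrid", kept = sum(inGrid),
                           rejected = sum(!inGrid)))
  df <- df[inGrid, , drop = FALSE]
  cell <- cell[inGrid]
  keep <- !duplicated(cell)
  prov <- rbind(prov, data.frame(stage = "thinToGrid", kept = sum(keep),
                                 rejected = sum(!keep)))
  df <- df[keep, , drop = FALSE]
  df$cell <- cell[keep]
  rownames(df) <- NULL
  new("OccurrenceSet", records = df, provenance = prov)
}

#' Read/write occurrence tables in the Darwin-Core-like CSV dialect
#'
#' @param path CSV path with headers decimalLongitude, decimalLatitude,
#'   year, coordinateUncertaintyInMeters, basisOfRecord (and species).
#' @param occ An \linkS4class{OccurrenceSet} or data frame.
#' @return \code{readOccurrences}: a data frame.
#' @export
readOccurrences <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readOccurrences
#' @export
writeOccurrences <- function(occ, path) {
  df <- if (is(occ, "OccurrenceSet")) occ@records else occ
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
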
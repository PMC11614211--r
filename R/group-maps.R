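# Group-level aggregation: significant-contact counts, region accuracy maps
# and the three time-frequency feature maps.

resultsTable <- function(results) {
  if (!length(results)) {
    return(data.frame(contact = character(), format = character(),
                      accuracy = numeric(), pValue = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  stopifnot(all(vapply(results, is, logical(1), "ContactResult")))
  df <- data.frame(
    contact = vapply(results, function(r) r@contact, ""),
    format = vapply(results, function(r) r@format, ""),
    accuracy = vapply(results, function(r) r@accuracy, 0),
    pValue = vapply(results, function(r) r@pValue, 0),
    significant = vapply(results, function(r) r@significant, NA),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("contact", "format")]))
    stopf("duplicate (contact, format) result pairs")
  df
}

#' Count significant contacts per format
#'
#' @param results list of [ContactResult-class] objects, one per
#'   contact x format.
#' @return a list: `perFormat` (named integer vector of significant-contact
#'   counts) and `intersection` (contacts significant in every per-format
#'   contrast, the `"all"` pooled contrast excluded).
#' @export
countSignificant <- function(results) {
  df <- resultsTable(results)
  fmts <- unique(df$format)
  perFormat <- vapply(fmts, function(f)
    sum(df$significant[df$format == f]), integer(1))
  interFmts <- setdiff(fmts, "all")
  inter <- 0L
  if (length(interFmts)) {
    contacts <- unique(df$contact)
    inter <- sum(vapply(contacts, function(ch) {
      sub <- df[df$contact == ch & df$format %in% interFmts, ]
      nrow(sub) == length(interFmts) && all(sub$significant)
    }, logical(1)))
  }
  list(perFormat = perFormat, intersection = as.integer(inter))
}

#' Aggregate decoding accuracy by anatomical region
#'
#' @param results list of [ContactResult-class] objects (typically one
#'   format).
#' @param electrodes electrode `data.frame` with columns `name`, `region`
#'   covering every contact.
#' @param aggregate `"max"` (default, matching the figures' gradients that
#'   start at the significance floor) or `"mean"`.
#' @return a `data.frame` with one row per region that has at least one
#'   significant contact: `region`, `accuracy` (aggregate over significant
#'   contacts), `nContacts` (contacts analyzed in the region),
#'   `nSignificant`.
#' @export
regionAccuracy <- function(results, electrodes, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  df <- resultsTable(results)
  miss <- setdiff(df$contact, electrodes$name)
  if (length(miss))
    stopf("contact(s) without a region label: %s", paste(miss, collapse = ", "))
  df$region <- electrodes$region[match(df$contact, electrodes$name)]
  regions <- sort(unique(df$region))
  out <- do.call(rbind, lapply(regions, function(rg) {
    sub <- df[df$region == rg, ]
    sig <- sub[sub$significant, ]
    if (!nrow(sig)) return(NULL)
    data.frame(region = rg,
               accuracy = if (aggregate == "max") max(sig$accuracy)
                          else mean(sig$accuracy),
               nContacts = nrow(sub), nSignificant = nrow(sig),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(region = character(), accuracy = numeric(),
                      nContacts = integer(), nSignificant = integer(),
                      stringsAsFactors = FALSE)
  out
}

#' Group-level time-frequency feature maps
#'
#' Aggregates significant clusters across contacts into three grids:
#' the proportion of analyzed contacts whose significant clusters cover each
#' time-frequency point; among covering contacts, the proportion whose
#' covering cluster is positive; and the mean cross-validated accuracy of
#' covering contacts. The latter two maps are `NA` (masked) wherever no
#' contact covers the point.
#'
#' @param results list of [ContactResult-class] objects for one format (the
#'   denominator of the proportion map is `length(results)`).
#' @param clusterSets named list, contact name -> [ClusterSet-class], for
#'   the contacts that were cluster-tested. All cluster grids must share one
#'   shape.
#' @param format format label recorded on the bundle.
#' @return a [FeatureMapBundle-class].
#' @export
featureMaps <- function(results, clusterSets, format = "all") {
  df <- resultsTable(results)
  if (!length(results)) stopf("no results to aggregate")
  nr <- length(results[[1]]@freqsHz) + 1L
  nt <- length(results[[1]]@timesS)
  nCover <- matrix(0, nr, nt)
  nPos <- matrix(0, nr, nt)
  accSum <- matrix(0, nr, nt)
  for (ch in names(clusterSets)) {
    cs <- clusterSets[[ch]]
    if (!is(cs, "ClusterSet")) stopf("'clusterSets' must contain ClusterSet objects")
    if (!identical(dim(cs@tMap), c(nr, nt)))
      stopf("cluster grid shape for '%s' does not match the feature space", ch)
    ri <- which(df$contact == ch)
    if (!length(ri)) stopf("cluster set for '%s' has no matching result", ch)
    acc <- df$accuracy[ri[1]]
    cover <- matrix(FALSE, nr, nt)
    pos <- matrix(FALSE, nr, nt)
    for (cl in significantClusters(cs)) {
      cover[cl$cells] <- TRUE
      if (cl$sign == "positive") pos[cl$cells] <- TRUE
    }
    nCover <- nCover + cover
    nPos <- nPos + pos
    accSum <- accSum + cover * acc
  }
  nContacts <- length(results)
  propSig <- nCover / nContacts
  propPos <- ifelse(nCover > 0, nPos / nCover, NA_real_)
  classVal <- ifelse(nCover > 0, accSum / nCover, NA_real_)
  new("FeatureMapBundle", proportionSignificant = propSig,
      proportionPositive = propPos, classificationValue = classVal,
      freqsHz = results[[1]]@freqsHz, timesS = results[[1]]@timesS,
      nContacts = as.integer(nContacts), format = format)
}
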
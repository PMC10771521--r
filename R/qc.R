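RATINGS_COLUMNS <- c("family_id", "individual_id", "twin_order", "zygosity",
                     "sex", "age", "domain", "image_id", "presentation", "rating")

#' Read and validate a long-format ratings CSV
#'
#' Expects the header
#' \code{family_id,individual_id,twin_order,zygosity,sex,age,domain,image_id,presentation,rating}.
#' Validation errors (missing columns, duplicate
#' individual/domain/image/presentation keys, out-of-scale ratings) are
#' reported with the offending rows.
#'
#' @param path CSV file path.
#' @param rating_scale declared scale bounds; set \code{bounded = FALSE} for
#'   continuous (unclipped) simulated ratings.
#' @param bounded enforce the scale bounds?
#' @return a validated \code{ratings_table} data.frame.
#' @export
read_ratings <- function(path, rating_scale = c(1, 7), bounded = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ratings(tab, rating_scale = rating_scale, bounded = bounded)
}

#' Validate an in-memory ratings table
#'
#' @param tab data.frame with the ratings columns.
#' @inheritParams read_ratings
#' @return the table, classed as \code{ratings_table}.
#' @export
validate_ratings <- function(tab, rating_scale = c(1, 7), bounded = TRUE) {
  missing_cols <- setdiff(RATINGS_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(tab$individual_id, tab$domain, tab$image_id, tab$presentation, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (individual_id, domain, image_id, presentation) key(s): ",
         paste(utils::head(key[dup], 3), collapse = "; "),
         " (rows ", paste(utils::head(which(dup), 3), collapse = ", "), ")")
  }
  if (!all(tab$zygosity %in% c("MZ", "DZ"))) stop("zygosity must be MZ or DZ")
  if (!all(tab$twin_order %in% c(1L, 2L))) stop("twin_order must be 1 or 2")
  if (!is.numeric(tab$rating)) stop("rating must be numeric")
  if (bounded) {
    bad <- which(tab$rating < rating_scale[1] | tab$rating > rating_scale[2])
    if (length(bad) > 0) {
      stop("rating outside declared scale [", rating_scale[1], ", ", rating_scale[2],
           "] at rows ", paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  n_per_fam <- tapply(tab$individual_id, tab$family_id, function(x) length(unique(x)))
  if (any(n_per_fam > 2)) {
    stop("more than two individuals in family ", names(which(n_per_fam > 2))[1])
  }
  class(tab) <- c("ratings_table", "data.frame")
  tab
}

# Repeated-image rating vectors (presentation 1 and 2) for one individual.
repeat_vectors <- function(tab, individual, domain = NULL) {
  sub <- tab[tab$individual_id == individual, ]
  if (!is.null(domain)) sub <- sub[sub$domain == domain, ]
  imgs <- intersect(sub$image_id[sub$presentation == 1], sub$image_id[sub$presentation == 2])
  p1 <- sub$rating[sub$presentation == 1][match(imgs, sub$image_id[sub$presentation == 1])]
  p2 <- sub$rating[sub$presentation == 2][match(imgs, sub$image_id[sub$presentation == 2])]
  list(images = imgs, p1 = p1, p2 = p2)
}

#' Intra-individual reliability of repeated ratings
#'
#' Pearson correlation between an individual's first- and second-presentation
#' ratings of the repeated images within one visual domain. Undefined
#' (returned as NA with a warning) when either presentation vector is
#' constant.
#'
#' @param tab a \code{ratings_table}.
#' @param individual individual id.
#' @param domain domain label (optional if the table holds one domain).
#' @return correlation in \code{[-1, 1]}, or NA when undefined.
#' @export
intra_individual_reliability <- function(tab, individual, domain = NULL) {
  rv <- repeat_vectors(tab, individual, domain)
  if (length(rv$images) < 3) {
    stop("fewer than 3 repeated images for individual ", individual)
  }
  if (stats::sd(rv$p1) == 0 || stats::sd(rv$p2) == 0) {
    warning("constant presentation vector for ", individual, ": reliability undefined")
    return(NA_real_)
  }
  stats::cor(rv$p1, rv$p2)
}

#' Intra-image reliability of repeated ratings
#'
#' Pearson correlation, across individuals, between first- and
#' second-presentation ratings of one repeated image.
#'
#' @param tab a \code{ratings_table}.
#' @param image image id.
#' @param domain domain label (optional).
#' @return correlation in \code{[-1, 1]}, or NA when undefined.
#' @export
intra_image_reliability <- function(tab, image, domain = NULL) {
  sub <- tab[tab$image_id == image, ]
  if (!is.null(domain)) sub <- sub[sub$domain == domain, ]
  ids <- intersect(sub$individual_id[sub$presentation == 1],
                   sub$individual_id[sub$presentation == 2])
  if (length(ids) < 3) stop("image ", image, " repeated for fewer than 3 individuals")
  p1 <- sub$rating[sub$presentation == 1][match(ids, sub$individual_id[sub$presentation == 1])]
  p2 <- sub$rating[sub$presentation == 2][match(ids, sub$individual_id[sub$presentation == 2])]
  if (stats::sd(p1) == 0 || stats::sd(p2) == 0) {
    warning("constant presentation vector for image ", image)
    return(NA_real_)
  }
  stats::cor(p1, p2)
}

#' Apply the rating-level exclusion rules
#'
#' Excludes, independently within each visual domain: (1) individuals whose
#' ratings have zero standard deviation; (2) individuals whose
#' intra-individual reliability over repeated images is below
#' \code{r_intra_min} (strict \code{<}; an undefined reliability from a
#' constant presentation vector also excludes, conservatively). A pair whose
#' other member survives is retained as an incomplete pair.
#'
#' @param tab a \code{ratings_table}.
#' @param r_intra_min reliability threshold (default 0.5).
#' @return list with the filtered \code{table} and a \code{report} containing
#'   per-domain exclusion counts and per-individual reliabilities.
#' @export
apply_exclusions <- function(tab, r_intra_min = 0.5) {
  keep <- rep(TRUE, nrow(tab))
  reports <- list()
  rel_rows <- list()
  for (dom in unique(tab$domain)) {
    in_dom <- tab$domain == dom
    sub <- tab[in_dom, ]
    ids <- unique(sub$individual_id)
    sds <- tapply(sub$rating, sub$individual_id, stats::sd)[ids]
    excl_sd <- ids[sds == 0]
    rel <- vapply(ids, function(id) {
      rv <- repeat_vectors(sub, id)
      if (length(rv$images) < 3) return(NA_real_)
      if (stats::sd(rv$p1) == 0 || stats::sd(rv$p2) == 0) return(NA_real_)
      stats::cor(rv$p1, rv$p2)
    }, numeric(1))
    has_repeats <- vapply(ids, function(id) {
      length(repeat_vectors(sub, id)$images) >= 3
    }, logical(1))
    # undefined reliability with repeats present -> conservative exclusion
    excl_rel <- ids[has_repeats & (is.na(rel) | rel < r_intra_min) & !(ids %in% excl_sd)]
    drop_ids <- union(excl_sd, excl_rel)
    keep[in_dom & tab$individual_id %in% drop_ids] <- FALSE
    reports[[dom]] <- data.frame(
      domain = dom, n_individuals = length(ids),
      excluded_zero_sd = length(excl_sd), excluded_low_reliability = length(excl_rel),
      retained = length(ids) - length(drop_ids), stringsAsFactors = FALSE
    )
    rel_rows[[dom]] <- data.frame(domain = dom, individual_id = ids,
                                  r_intra = unname(rel), stringsAsFactors = FALSE)
  }
  out <- tab[keep, ]
  class(out) <- c("ratings_table", "data.frame")
  list(table = out,
       report = list(counts = do.call(rbind, reports),
                     reliabilities = do.call(rbind, rel_rows)))
}

#' Metric-level outlier filter (3 x IQR fence)
#'
#' Flags values outside the two-sided Tukey fence
#' \code{[Q1 - mult*IQR, Q3 + mult*IQR]} (type-7 quartiles). With an all-equal
#' sample the IQR is zero and nothing is excluded. \code{one_sided = TRUE}
#' applies only the upper fence.
#'
#' @param values numeric vector (NA values are retained in the mask as NA).
#' @param mult fence multiplier (default 3).
#' @param one_sided apply the upper fence only?
#' @return logical mask, TRUE = retained.
#' @export
metric_outlier_filter <- function(values, mult = 3, one_sided = FALSE) {
  finite <- values[is.finite(values)]
  if (length(finite) < 4) stop("need at least 4 finite values")
  q <- stats::quantile(finite, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- if (one_sided) -Inf else q[1] - mult * iqr
  hi <- q[2] + mult * iqr
  if (iqr == 0) return(rep(TRUE, length(values)))
  values >= lo & values <= hi
}

#' Average repeated presentations into an individuals x images matrix
#'
#' @param tab a QC-filtered \code{ratings_table} holding a single domain.
#' @return a numeric matrix (rows = individuals, columns = images) of class
#'   \code{rating_matrix}, with per-individual metadata in
#'   \code{attr(, "meta")}. Cells are means over that individual's
#'   presentations of the image; images an individual never rated are NA.
#' @export
average_repeats <- function(tab) {
  if (length(unique(tab$domain)) != 1) {
    stop("average_repeats expects a single domain; split the table first")
  }
  ids <- unique(tab$individual_id)
  imgs <- sort(unique(tab$image_id))
  m <- matrix(NA_real_, length(ids), length(imgs), dimnames = list(ids, imgs))
  agg <- stats::aggregate(rating ~ individual_id + image_id, data = tab, FUN = mean)
  m[cbind(match(agg$individual_id, ids), match(agg$image_id, imgs))] <- agg$rating
  first <- tab[!duplicated(tab$individual_id), ]
  meta <- data.frame(
    individual_id = first$individual_id, family_id = first$family_id,
    twin_order = first$twin_order, zygosity = first$zygosity,
    sex = first$sex, age = first$age, stringsAsFactors = FALSE
  )
  meta <- meta[match(ids, meta$individual_id), ]
  rownames(meta) <- NULL
  structure(m, meta = meta, domain = tab$domain[1], class = c("rating_matrix", "matrix"))
}
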
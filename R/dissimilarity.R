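# Compositional dissimilarity matrix between the nine base ecosystem types.

# Source categories of the field-survey dissimilarity table (1 - Sorensen
# between land-use classes) from which the 9 x 9 matrix is assembled.
.SOURCE_CATEGORIES <- c(
  "primary vegetation", "mature secondary vegetation",
  "intermediate secondary vegetation", "young secondary vegetation",
  "plantation forest", "cropland", "pasture", "urban"
)

# Which source categories stand for each base ecosystem type. Forested and
# non-forested primary land share the "primary vegetation" values (assumed
# similar species composition); managed pasture and rangeland share the
# "pasture" values; non-forested secondary is the average of the intermediate
# and young secondary rows; forested secondary is mature secondary.
.BASE9_SOURCES <- list(
  primary_forested = "primary vegetation",
  primary_nonforested = "primary vegetation",
  secondary_forested = "mature secondary vegetation",
  secondary_nonforested = c("intermediate secondary vegetation",
                            "young secondary vegetation"),
  pasture = "pasture",
  rangeland = "pasture",
  urban = "urban",
  cropland = "cropland",
  tree_plantation = "plantation forest"
)

#' Build the 9 x 9 compositional dissimilarity matrix
#'
#' Assembles pairwise compositional distances `d_ij` between the nine base
#' ecosystem types from a source table of 1 - Sorensen dissimilarities among
#' field-survey land-use categories. Each base type maps to one or more source
#' categories (see Details); `d_ij` is the mean of the source values over the
#' mapped category pairs, the diagonal is 0, and all entries are rescaled by
#' the global off-diagonal maximum so that `max(d_ij) = 1`.
#'
#' @details Mapping rules: both primary types share the "primary vegetation"
#' values (so `d` between them is 0); pasture and rangeland share the
#' "pasture" values; non-forested secondary takes the average of the
#' "intermediate" and "young" secondary vegetation rows; forested secondary
#' is "mature secondary vegetation"; cropland, plantation and urban map
#' directly.
#'
#' @param sourceTable Either a long `data.frame` with columns `category_i`,
#'   `category_j`, `d`, or a symmetric matrix with source-category dimnames.
#' @return Symmetric 9 x 9 numeric matrix over the base ecosystem types, with
#'   zero diagonal, entries in `[0, 1]` and off-diagonal maximum exactly 1.
#' @seealso [defaultDissimilarityMatrix()], [raoQ()]
#' @export
buildDissimilarityMatrix <- function(sourceTable) {
  if (is.data.frame(sourceTable)) {
    need <- c("category_i", "category_j", "d")
    if (!all(need %in% names(sourceTable))) {
      .err("ecodivMappingError",
           "source table needs columns category_i, category_j, d")
    }
    cats <- sort(unique(c(sourceTable$category_i, sourceTable$category_j)))
    S <- matrix(NA_real_, length(cats), length(cats), dimnames = list(cats, cats))
    diag(S) <- 0
    for (r in seq_len(nrow(sourceTable))) {
      i <- sourceTable$category_i[r]
      j <- sourceTable$category_j[r]
      S[i, j] <- S[j, i] <- sourceTable$d[r]
    }
  } else if (is.matrix(sourceTable)) {
    S <- sourceTable
    if (is.null(rownames(S)) || !isSymmetric(unname(S))) {
      .err("ecodivMappingError", "source matrix must be symmetric with dimnames")
    }
    diag(S) <- 0
  } else {
    .err("ecodivMappingError", "source table must be a data.frame or matrix")
  }
  missing <- setdiff(.SOURCE_CATEGORIES, rownames(S))
  if (length(missing)) {
    .err("ecodivMappingError", "source table lacks category(ies): %s",
         paste(missing, collapse = ", "))
  }
  if (anyNA(S[.SOURCE_CATEGORIES, .SOURCE_CATEGORIES])) {
    .err("ecodivMappingError", "source table has missing pairwise values")
  }
  if (any(S < 0) || any(S > 1)) {
    .err("ecodivMappingError", "source dissimilarities must lie in [0, 1]")
  }
  D <- matrix(0, 9, 9, dimnames = list(.BASE9, .BASE9))
  for (i in seq_len(9)) {
    for (j in seq_len(9)) {
      if (i == j) next
      D[i, j] <- mean(S[.BASE9_SOURCES[[.BASE9[i]]],
                        .BASE9_SOURCES[[.BASE9[j]]]])
    }
  }
  mx <- max(D)
  if (mx <= 0) {
    .err("ecodivMappingError", "all source dissimilarities are zero")
  }
  D <- D / mx
  diag(D) <- 0
  D
}

#' Default compositional dissimilarity matrix
#'
#' Builds the 9 x 9 matrix from the synthetic source table shipped with the
#' package (`inst/extdata/source_dissimilarity_synthetic.csv`) — a plausible
#' stand-in encoding the documented mapping rules, not empirical survey
#' values. Supply your own table to [buildDissimilarityMatrix()] to use an
#' empirically derived matrix.
#'
#' @return Symmetric 9 x 9 matrix over the base ecosystem types.
#' @export
defaultDissimilarityMatrix <- function() {
  path <- system.file("extdata", "source_dissimilarity_synthetic.csv",
                      package = "ecodivgrid", mustWork = TRUE)
  buildDissimilarityMatrix(utils::read.csv(path, stringsAsFactors = FALSE))
}

# Strip the "@GLOBAL" suffix of base9 ecosystem ids; error on biome-crossed
# ids, for which no cross-biome dissimilarity is defined.
.alignDissimilarity <- function(labels, d) {
  base <- sub("@GLOBAL$", "", labels)
  if (!all(base %in% rownames(d))) {
    .err("ecodivMappingError",
         "type(s) %s absent from the dissimilarity matrix (Rao's Q is defined for the base9 scheme only)",
         paste(setdiff(base, rownames(d)), collapse = ", "))
  }
  d[base, base, drop = FALSE]
}
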
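#' k-nearest-neighbour imputation of a covariate table
#'
#' Fills missing cells using the k nearest rows under Euclidean distance on
#' the standardized numeric columns, skipping missing dimensions pairwise
#' (the squared differences over shared observed dimensions are averaged
#' before taking the square root, so rows with different missingness
#' patterns remain comparable). Numeric gaps are filled with the mean of the
#' k neighbours' values; categorical gaps with their mode (ties broken by
#' alphabetical order). Observed cells are never altered.
#'
#' @param table Tibble; an optional `participant_id` column is carried
#'   through untouched.
#' @param k Number of neighbours (default 5).
#' @return The table with every fillable missing cell imputed.
#' @export
impute_knn <- function(table, k = 5) {
  stopifnot(k >= 1)
  id_col <- intersect("participant_id", names(table))
  vars <- setdiff(names(table), id_col)
  num_vars <- vars[vapply(table[vars], is.numeric, logical(1))]
  cat_vars <- setdiff(vars, num_vars)

  all_missing <- vars[vapply(table[vars], function(x) all(is.na(x)), logical(1))]
  if (length(all_missing) > 0) {
    stop("impute_knn: column(s) entirely missing: ",
         paste(all_missing, collapse = ", "))
  }
  if (!anyNA(table[vars])) return(table)

  z <- scale(as.matrix(table[num_vars]))
  n <- nrow(table)

  nearest <- function(i, have_col) {
    shared <- !is.na(z) & matrix(rep(!is.na(z[i, ]), each = n), nrow = n)
    sq <- sweep(z, 2, z[i, ], "-")^2
    sq[!shared] <- NA
    nshared <- rowSums(shared)
    d <- sqrt(rowMeans(sq, na.rm = TRUE))
    d[i] <- Inf
    d[nshared == 0] <- Inf
    d[!have_col] <- Inf
    order(d)[seq_len(k)][is.finite(sort(d)[seq_len(k)])]
  }

  out <- table
  for (v in vars) {
    holes <- which(is.na(table[[v]]))
    if (length(holes) == 0) next
    have <- !is.na(table[[v]])
    for (i in holes) {
      nb <- nearest(i, have)
      if (length(nb) == 0) next
      vals <- table[[v]][nb]
      out[[v]][i] <- if (v %in% num_vars) {
        mean(vals)
      } else {
        tab <- table(vals)  # names alphabetical; which.max takes the first tie
        names(tab)[which.max(tab)]
      }
    }
  }
  out
}
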
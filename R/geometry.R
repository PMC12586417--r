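#' Geometry of a continuous rating line
#'
#' A rating line of length `length` with midpoint `midpoint`. Responses live
#' on the closed interval `[midpoint - length/2, midpoint + length/2]`;
#' endpoint marks are legal responses (the closed response situation), so no
#' boundary transformation of the data is ever needed.
#'
#' @param length Positive line length `L`, in the units the scale was scored
#'   in (pixels, centimetres, unit interval, ...).
#' @param midpoint Midpoint `c` of the line, same units. Defaults to `length/2`
#'   so that `scale_geometry(L)` describes a line scored from 0 to `L`.
#' @return An object of class `scale_geometry` with fields `length`,
#'   `midpoint`, `lower`, `upper`.
#' @examples
#' scale_geometry(800)           # a 0-800 pixel VAS line
#' scale_geometry(1, 0.5)        # the unit interval
#' @export
scale_geometry <- function(length, midpoint = length / 2) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
    length <= 0) {
    stop("`length` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(midpoint) || length(midpoint) != 1L || !is.finite(midpoint)) {
    stop("`midpoint` must be a single finite number.", call. = FALSE)
  }
  structure(
    list(
      length = as.numeric(length),
      midpoint = as.numeric(midpoint),
      lower = midpoint - length / 2,
      upper = midpoint + length / 2
    ),
    class = "scale_geometry"
  )
}

#' @export
print.scale_geometry <- function(x, ...) {
  cat(sprintf(
    "<scale_geometry> L = %g, c = %g, support [%g, %g]\n",
    x$length, x$midpoint, x$lower, x$upper
  ))
  invisible(x)
}

.as_geometry <- function(geom) {
  if (inherits(geom, "scale_geometry")) {
    return(geom)
  }
  if (is.numeric(geom) && length(geom) == 2L) {
    return(scale_geometry(diff(geom), mean(geom)))
  }
  stop("`geom` must be a scale_geometry or a numeric range c(min, max).",
    call. = FALSE
  )
}

.check_theta <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta <= 0)) {
    stop("`theta` must be strictly positive.", call. = FALSE)
  }
  invisible(theta)
}

# Coerce a wide response table (data frame with optional id column, or
# matrix) into a numeric matrix plus ids and item names. Blank cells are
# missing responses.
.as_response_matrix <- function(data, id_col = NULL) {
  if (is.matrix(data)) {
    x <- data
    storage.mode(x) <- "double"
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
    items <- colnames(x) %||% paste0("item_", seq_len(ncol(x)))
  } else if (is.data.frame(data)) {
    df <- data
    if (is.null(id_col)) {
      # treat a leading non-numeric column (or one literally named id) as ids
      first_chr <- ncol(df) > 0 &&
        (!is.numeric(df[[1]]) || tolower(names(df)[1]) %in% c("id", "person"))
      id_col <- if (first_chr) names(df)[1] else NA_character_
    }
    if (!is.na(id_col) && id_col %in% names(df)) {
      ids <- as.character(df[[id_col]])
      df <- df[setdiff(names(df), id_col)]
    } else {
      ids <- as.character(seq_len(nrow(df)))
    }
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    if (length(bad)) {
      stop("Non-numeric item column(s): ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    x <- as.matrix(df)
    items <- names(df)
  } else {
    stop("`data` must be a data frame or a numeric matrix.", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("Need at least one person and one item.", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("Duplicate person ids.", call. = FALSE)
  list(x = x, ids = ids, items = items)
}

.check_support <- function(x, geom, tol = 1e-8) {
  bad <- which(!is.na(x) & (x < geom$lower - tol | x > geom$upper + tol),
    arr.ind = TRUE
  )
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "Response out of the declared support [%g, %g]: value %g at row %d, column %d.",
      geom$lower, geom$upper, x[bad[1, , drop = FALSE]], bad[1, 1], bad[1, 2]
    ), call. = FALSE)
  }
  invisible(x)
}

#' Affinely rescale observed scores between ranges
#'
#' Maps every non-missing score from `from_range` to `to_range` by the affine
#' transformation that sends the endpoints of one range to the endpoints of
#' the other. Used to move data between the recorded scoring unit (say 0-800
#' pixels) and the unit interval; missingness is preserved and endpoint
#' values map to endpoint values exactly.
#'
#' @param data Wide response table: data frame (optional id column) or matrix.
#' @param from_range,to_range Length-2 numeric ranges `c(min, max)`.
#' @return A tibble with the same id/item columns, scores rescaled.
#' @examples
#' rescale_scores(data.frame(id = "a", q1 = 400), c(0, 800), c(0, 1))
#' @export
rescale_scores <- function(data, from_range, to_range) {
  stopifnot(length(from_range) == 2L, length(to_range) == 2L)
  rm_ <- .as_response_matrix(data)
  geom <- scale_geometry(diff(from_range), mean(from_range))
  bad <- which(!is.na(rm_$x) & (rm_$x < from_range[1] | rm_$x > from_range[2]),
    arr.ind = TRUE
  )
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "Value %g (person %s, item %s) outside from_range [%g, %g].",
      rm_$x[bad[1, , drop = FALSE]], rm_$ids[bad[1, 1]], rm_$items[bad[1, 2]],
      from_range[1], from_range[2]
    ), call. = FALSE)
  }
  scaled <- (rm_$x - from_range[1]) / diff(from_range) * diff(to_range) +
    to_range[1]
  out <- tibble::as_tibble(as.data.frame(scaled))
  names(out) <- rm_$items
  dplyr::bind_cols(tibble::tibble(id = rm_$ids), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
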
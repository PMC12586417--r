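#' Declare the properties of a rating dataset
#'
#' Mirrors the information a user supplies before an analysis: whether the
#' scores are continuous or discrete, the original score range used during
#' data collection (0-800 pixels, 1-5 Likert, ...), the model variant, and
#' the id column of the data file.
#'
#' @param data_kind `"continuous"` or `"discrete"`.
#' @param score_min,score_max Original score range.
#' @param n_categories Category count, required for discrete data.
#' @param model_variant `"muller"` or `"verhelst"`.
#' @param id_col Name of the person-id column in the data file.
#' @return A list of class `dataset_declaration`.
#' @export
dataset_declaration <- function(data_kind = c("continuous", "discrete"),
                                score_min, score_max, n_categories = NULL,
                                model_variant = c("muller", "verhelst"),
                                id_col = "id") {
  data_kind <- match.arg(data_kind)
  model_variant <- match.arg(model_variant)
  if (!is.numeric(score_min) || !is.numeric(score_max) ||
    score_min >= score_max) {
    stop("Need score_min < score_max.", call. = FALSE)
  }
  if (data_kind == "discrete") {
    if (is.null(n_categories) || n_categories < 2) {
      stop("Discrete data need n_categories >= 2.", call. = FALSE)
    }
  }
  structure(
    list(
      data_kind = data_kind, score_min = score_min, score_max = score_max,
      n_categories = n_categories, model_variant = model_variant,
      id_col = id_col
    ),
    class = "dataset_declaration"
  )
}

#' Read a wide-format rating data file
#'
#' The template layout: comma-separated UTF-8 text, a header row, the first
#' column person ids, the remaining columns one item each. Blank cells are
#' missing responses. Every value is validated against the declared range
#' (the offending row and column are named on failure).
#'
#' @param path File path.
#' @param declaration A [dataset_declaration()].
#' @return A list with `responses` (wide tibble), `geometry`
#'   (a [scale_geometry()] for the declared range) and `declaration`.
#' @export
read_template <- function(path, declaration) {
  stopifnot(inherits(declaration, "dataset_declaration"))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!declaration$id_col %in% names(df)) {
    stop(sprintf("Id column '%s' not found.", declaration$id_col),
      call. = FALSE
    )
  }
  rm_ <- .as_response_matrix(df, id_col = declaration$id_col)
  rng <- c(declaration$score_min, declaration$score_max)
  bad <- which(!is.na(rm_$x) & (rm_$x < rng[1] | rm_$x > rng[2]),
    arr.ind = TRUE
  )
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "Value %g outside declared range [%g, %g] (person %s, item %s).",
      rm_$x[bad[1, , drop = FALSE]], rng[1], rng[2],
      rm_$ids[bad[1, 1]], rm_$items[bad[1, 2]]
    ), call. = FALSE)
  }
  list(
    responses = dplyr::bind_cols(
      tibble::tibble(id = rm_$ids),
      tibble::as_tibble(as.data.frame(rm_$x))
    ),
    geometry = scale_geometry(diff(rng), mean(rng)),
    declaration = declaration
  )
}

#' Write a blank data-file template
#'
#' Emits the expected layout — an `id` column followed by one column per
#' item — with a few example rows of valid scores.
#'
#' @param path Output path.
#' @param n_items Number of item columns.
#' @param score_range Example score range for the sample rows.
#' @return The path, invisibly.
#' @export
write_template <- function(path, n_items = 5, score_range = c(0, 100)) {
  stopifnot(n_items >= 1)
  ex <- matrix(
    round(seq(score_range[1], score_range[2], length.out = 3 * n_items), 2),
    nrow = 3
  )
  df <- dplyr::bind_cols(
    tibble::tibble(id = paste0("person_", 1:3)),
    tibble::as_tibble(as.data.frame(ex, col.names = NULL))
  )
  names(df) <- c("id", paste0("item_", seq_len(n_items)))
  readr::write_csv(df, path)
  invisible(path)
}

#' Write fit results as delimited text files
#'
#' Four files mirror the analysis report: `summary.csv` (descriptive
#' statistics of the ability estimates, the dispersion estimate and run
#' metadata), `items.csv` (difficulties with standard errors, plus step
#' difficulties for discrete fits), `persons.csv` (abilities with posterior
#' SDs), and `fit.csv` (outfit statistics with the retention flag).
#'
#' @param fit A `corsm_fit`.
#' @param dir Output directory (created if absent).
#' @param seed Optional seed to echo into the run metadata.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(fit, dir, seed = NA) {
  stopifnot(inherits(fit, "corsm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- fit$persons$ability
  summary_df <- tibble::tibble(
    statistic = c(
      "n_persons", "n_items", "ability_mean", "ability_sd",
      "ability_min", "ability_max", "dispersion_mean", "log_likelihood",
      "converged", "cycles", "seed"
    ),
    value = c(
      nrow(fit$persons), nrow(fit$items), mean(ab), stats::sd(ab),
      min(ab), max(ab), mean(fit$dispersion$theta), fit$logLik,
      as.numeric(fit$converged), fit$cycles, as.numeric(seed)
    )
  )
  items_df <- fit$items
  if (!is.null(fit$steps)) {
    items_df <- dplyr::bind_rows(
      items_df,
      tibble::tibble(
        item = paste0("step_", fit$steps$step),
        difficulty = fit$steps$tau, se = NA_real_
      )
    )
  }
  paths <- c(
    summary = file.path(dir, "summary.csv"),
    items = file.path(dir, "items.csv"),
    persons = file.path(dir, "persons.csv"),
    fit = file.path(dir, "fit.csv")
  )
  readr::write_csv(summary_df, paths["summary"])
  readr::write_csv(items_df, paths["items"])
  readr::write_csv(fit$persons, paths["persons"])
  readr::write_csv(outfit_mnsq(fit), paths["fit"])
  invisible(paths)
}
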
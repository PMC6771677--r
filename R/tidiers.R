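# broom-style tidiers for fitted ensembles and evaluation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ensemble: one row per member
#'
#' @param x An `mpra_ensemble`.
#' @param ... Unused.
#' @return A tibble `member`, `kind`, `n_estimators`.
#' @method tidy mpra_ensemble
#' @export
tidy.mpra_ensemble <- function(x, ...) {
  tibble::tibble(
    member = x$member_ids,
    kind = vapply(x$members, `[[`, "", "kind"),
    n_estimators = ifelse(x$member_ids == "enet", NA_integer_,
                          x$spec$n_estimators)
  )
}

#' Glance at an ensemble
#'
#' @param x An `mpra_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance mpra_ensemble
#' @export
glance.mpra_ensemble <- function(x, ...) {
  tibble::tibble(task = x$task, n_members = length(x$members),
                 n_features = length(x$feature_names),
                 n_estimators = x$spec$n_estimators,
                 shuffled = x$shuffled)
}

#' Tidy an evaluation: one row per fold per test
#'
#' @param x An `mpra_eval` from [cross_validate()] or
#'   [cross_dataset_evaluate()].
#' @param ... Unused.
#' @return A tibble `fold`, `test`, `statistic`.
#' @method tidy mpra_eval
#' @export
tidy.mpra_eval <- function(x, ...) {
  dplyr::select(x$folds, "fold", "test", "statistic",
                dplyr::any_of(c("p", "flagged")))
}

#' Glance at an evaluation: aggregate mean and sd per test
#'
#' @param x An `mpra_eval`.
#' @param ... Unused.
#' @return A tibble `test`, `mean`, `sd`, `n_folds`.
#' @method glance mpra_eval
#' @export
glance.mpra_eval <- function(x, ...) {
  x$summary
}
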
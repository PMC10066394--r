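#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted vigilance MLP
#'
#' @param x A `vigilance_mlp`.
#' @param ... Unused.
#' @return Tibble with one row per training pass: `pass`, `train_loss`,
#'   `validation_loss`.
#' @export
tidy.vigilance_mlp <- function(x, ...) x$history

#' One-row summary of a fitted vigilance MLP
#'
#' @param x A `vigilance_mlp`.
#' @param ... Unused.
#' @return One-row tibble: sizes, passes run, best pass, best validation
#'   loss, and whether early stopping fired before the pass cap.
#' @export
glance.vigilance_mlp <- function(x, ...) {
  tibble::tibble(
    input_size = x$config$input_size,
    hidden_size = x$config$hidden_size,
    output_size = x$config$output_size,
    n_train = x$n_train,
    n_validation = x$n_validation,
    passes_run = nrow(x$history),
    best_pass = x$best_pass,
    best_validation_loss = x$best_validation_loss,
    early_stopped = nrow(x$history) < x$config$max_iterations
  )
}

#' Tidy per-class metrics of a classifier evaluation
#'
#' @param x A `classifier_evaluation`.
#' @param ... Unused.
#' @return Tibble with one row per state: `state`, `n_true`, `precision`,
#'   `recall`, `f1`.
#' @export
tidy.classifier_evaluation <- function(x, ...) {
  cm <- x$confusion
  tp <- diag(cm)
  tibble::tibble(
    state = factor(rownames(cm), levels = vigilance_states()),
    n_true = rowSums(cm),
    precision = ifelse(colSums(cm) > 0, tp / colSums(cm), 0),
    recall = ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0),
    f1 = unname(x$f1)
  )
}

#' One-row summary of a classifier evaluation
#'
#' @param x A `classifier_evaluation`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `accuracy`, `macro_f1`.
#' @export
glance.classifier_evaluation <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, macro_f1 = x$macro_f1)
}
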
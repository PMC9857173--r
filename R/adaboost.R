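# Discrete AdaBoost (two-class SAMME) on rpart decision stumps. Weak learners
# are depth-1 classification trees refit on exponentially reweighted cases;
# the ensemble predicts by the alpha-weighted vote. Implemented in-package
# because the surrounding toolchain provides bagging and gradient boosting
# but not classical adaptive boosting.

#' Fit a discrete AdaBoost ensemble of decision stumps
#'
#' @param x Numeric matrix or data frame of predictors.
#' @param y Factor with exactly two levels.
#' @param n_rounds Maximum number of boosting rounds (weak learners).
#' @param maxdepth Depth of each weak learner (1 = stump).
#' @return An `ada_boost` model (stumps, round weights `alpha`, class levels).
#' @export
ada_boost <- function(x, y, n_rounds = 50L, maxdepth = 1L) {
  y <- as.factor(y)
  if (nlevels(y) != 2L)
    stop_idscreen("idscreen_contract_error",
                  "ada_boost needs exactly 2 classes, got %d", nlevels(y))
  d <- data.frame(.y = y, as.data.frame(x), check.names = TRUE)
  n <- nrow(d)
  w <- rep(1 / n, n)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, d, type = "class")
    mis <- pred != y
    err <- sum(w[mis])
    if (err >= 0.5) break               # weak learner no better than chance
    if (err <= 0) {                     # perfect stump: cap its vote
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 0.5 * log((1 - 1e-10) / 1e-10))
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(ifelse(mis, alpha, -alpha))
    w <- w / sum(w)
  }
  if (!length(stumps)) {                # nothing learnable: majority class
    stumps <- list(NULL)
    alphas <- 1
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y),
                 majority = levels(y)[which.max(tabulate(y))],
                 n_rounds = n_rounds, maxdepth = maxdepth),
            class = "ada_boost")
}

#' @export
print.ada_boost <- function(x, ...) {
  cat(sprintf("<ada_boost> %d stump(s), classes: %s\n",
              length(x$stumps), paste(x$levels, collapse = " / ")))
  invisible(x)
}

#' Predict classes with an AdaBoost ensemble
#' @param object An `ada_boost` model.
#' @param newdata Predictors with the training columns.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.ada_boost <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata, check.names = TRUE)
  score <- rep(0, nrow(nd))
  for (m in seq_along(object$stumps)) {
    fit <- object$stumps[[m]]
    if (is.null(fit)) {                 # degenerate model: constant vote
      vote <- ifelse(object$majority == object$levels[2L], 1, -1)
      score <- score + object$alphas[m] * vote
    } else {
      pred <- predict(fit, nd, type = "class")
      score <- score + object$alphas[m] * ifelse(pred == object$levels[2L], 1, -1)
    }
  }
  factor(ifelse(score > 0, object$levels[2L], object$levels[1L]),
         levels = object$levels)
}
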
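#' Plot training history of a fitted classifier
#'
#' Two-panel base-graphics plot: loss and weighted F1 over epochs for the
#' training and validation splits.
#'
#' @param x a trained `femg_model`.
#' @param ... unused.
#' @export
plot.femg_model <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "loss", main = "loss")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_wf1, h$val_wf1), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "weighted F1", main = "weighted F1")
  invisible(x)
}

#' Boxplot of PCA scores by scene
#'
#' @param x a `femg_pca` result.
#' @param scenes scene label per observation (rows of the score matrix).
#' @param component which component to plot.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.femg_pca <- function(x, scenes, component = 1, ...) {
  sc <- factor(as.character(scenes),
               levels = intersect(scene_levels(), unique(scenes)))
  graphics::boxplot(x$scores[, component] ~ sc,
                    xlab = "scene",
                    ylab = colnames(x$loadings)[component], ...)
  invisible(x)
}
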
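#' Channel, expression, and scene taxonomies
#'
#' The pipeline works on 7-channel facial EMG amplitude recordings. The
#' channel order is fixed everywhere (files, matrices, model inputs):
#' corrugator (single central channel), then left/right frontalis,
#' left/right orbicularis, left/right zygomaticus.
#'
#' @return `femg_channels()` returns the 7 channel names in canonical order.
#' @export
femg_channels <- function() {
  c("corrugator_center",
    "frontalis_left", "frontalis_right",
    "orbicularis_left", "orbicularis_right",
    "zygomaticus_left", "zygomaticus_right")
}

#' @rdname femg_channels
#' @return `channel_muscle_group()` returns the muscle group of each channel.
#' @export
channel_muscle_group <- function() {
  ch <- femg_channels()
  structure(sub("_(center|left|right)$", "", ch), names = ch)
}

#' @rdname femg_channels
#' @return `expression_levels()` returns the 4 expression classes in canonical
#'   order (`neutral` first; this order is also the argmax tie-break order).
#' @export
expression_levels <- function() {
  c("neutral", "smile", "frown", "raised_eyebrow")
}

#' @rdname femg_channels
#' @return `scene_levels()` returns the scene labels; `baseline` is the
#'   reference condition for all delta computations.
#' @export
scene_levels <- function() {
  c("baseline", "emotional", "cognitive", "physical", "dual", "recovery")
}

#' FACS muscle-expression involvement map
#'
#' Boolean table stating which muscle groups are primarily involved in each
#' expression: smile engages orbicularis + zygomaticus, frown engages
#' frontalis + corrugator, a raised eyebrow engages the frontalis, and the
#' neutral face engages none.
#'
#' @return Logical matrix, rows = expressions, columns = muscle groups.
#' @export
muscle_expression_map <- function() {
  groups <- c("frontalis", "corrugator", "orbicularis", "zygomaticus")
  m <- matrix(FALSE, nrow = 4, ncol = 4,
              dimnames = list(expression_levels(), groups))
  m["smile", c("orbicularis", "zygomaticus")] <- TRUE
  m["frown", c("frontalis", "corrugator")] <- TRUE
  m["raised_eyebrow", "frontalis"] <- TRUE
  m
}

#' Channels involved in an expression
#'
#' @param expression one of [expression_levels()].
#' @return Character vector of channel names whose muscle group is involved.
#' @export
involved_channels <- function(expression) {
  expression <- match.arg(expression, expression_levels())
  map <- muscle_expression_map()
  grp <- channel_muscle_group()
  names(grp)[map[expression, grp]]
}

as_expression_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x), expression_levels())
  if (length(bad) > 0)
    stop("unknown expression label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = expression_levels())
}

# Evaluate expr with a temporarily seeded RNG, restoring prior state so
# generators are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a reproducible sub-seed
#'
#' Deterministically derives an integer seed below 2^31 from a base seed and
#' any number of string/integer qualifiers (a small polynomial hash), so
#' that pipeline stages and per-participant draws can be rerun in isolation
#' reproducibly from one global seed.
#'
#' @param seed base integer seed.
#' @param ... qualifiers (coerced to character).
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    for (cp in utf8ToInt(p)) h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}
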
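## One-dimensional topological persistence of local maxima.
##
## A superlevel-set filtration sweeps the level from +Inf downwards. Each new
## connected component is born at a local maximum; when two components merge
## at a saddle, the one whose maximum is lower dies there (elder rule) and is
## assigned persistence = birth - death. The component of the global maximum
## never dies and is flagged "essential", with persistence measured down to
## the global minimum.
##
## Deterministic tie-breaks, shared with the brute-force oracle:
##   * a plateau (run of equal values) counts as one extremum at its leftmost
##     index;
##   * when two maxima of equal height merge, the leftmost survives.

check_profile <- function(values) {
  if (length(values) == 0L) stop("profile must be non-empty")
  if (!all(is.finite(values))) stop("profile values must be finite")
  as.numeric(values)
}

persistence_frame <- function(position, birth, death, essential) {
  out <- data.frame(position = as.integer(position), birth = birth,
                    death = death, persistence = birth - death,
                    essential = essential)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Persistent local maxima of a 1-D profile
#'
#' Runs a union-find superlevel-set filtration over the profile and returns
#' every local maximum whose topological persistence (birth minus merge level)
#' reaches `threshold`. The global maximum is always returned: its component
#' never merges, so it is flagged `essential` and its persistence is taken
#' down to the global minimum of the profile.
#'
#' The threshold is interpreted on the profile's own scale; callers that pass
#' profiles rescaled to `[0, 1]` therefore express it as a fraction of the
#' profile maximum (the default 0.04 = 4%).
#'
#' @param values Numeric profile (finite, length >= 1).
#' @param threshold Minimum persistence for a maximum to be reported (>= 0).
#' @return A data frame sorted by `position` (1-based index into `values`)
#'   with columns `position`, `birth`, `death`, `persistence`, `essential`.
#' @seealso [brute_force_maxima()] for the quadratic reference implementation.
#' @examples
#' persistent_maxima(c(0, 1, 0.4, 0.8, 0), threshold = 0.2)
#' @export
persistent_maxima <- function(values, threshold = 0.04) {
  values <- check_profile(values)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  n <- length(values)

  ord <- order(-values, seq_len(n))  # descending level, ties left-to-right
  parent <- integer(n)               # 0 = not yet in the filtration
  peak <- integer(n)                 # root -> index of the component's maximum

  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }

  pos <- integer(0); birth <- numeric(0); death <- numeric(0)
  for (i in ord) {
    lp <- if (i > 1L && parent[i - 1L] != 0L) find(i - 1L) else 0L
    rp <- if (i < n && parent[i + 1L] != 0L) find(i + 1L) else 0L
    if (lp == 0L && rp == 0L) {        # born: new component
      parent[i] <- i
      peak[i] <- i
    } else if (lp != 0L && rp != 0L) { # saddle: two components merge
      pl <- peak[lp]; pr <- peak[rp]
      if (values[pl] > values[pr] || (values[pl] == values[pr] && pl < pr)) {
        win <- lp; lose <- rp
      } else {
        win <- rp; lose <- lp
      }
      pos <- c(pos, peak[lose])
      birth <- c(birth, values[peak[lose]])
      death <- c(death, values[i])
      parent[lose] <- win
      parent[i] <- win
    } else {                           # grow an existing component
      parent[i] <- max(lp, rp)
    }
  }

  root <- find(ord[1L])
  ess_pos <- peak[root]
  out <- persistence_frame(
    position = c(pos, ess_pos),
    birth = c(birth, values[ess_pos]),
    death = c(death, min(values)),
    essential = c(rep(FALSE, length(pos)), TRUE)
  )
  ## zero-persistence classes are diagonal pairs (a plateau flowing into a
  ## higher region), not local maxima: always discarded
  out <- out[out$essential |
               (out$persistence > 0 & out$persistence >= threshold), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Brute-force reference for [persistent_maxima()]
#'
#' Quadratic reference implementation used as an independent oracle: local
#' maxima are enumerated directly (a plateau is represented by its leftmost
#' index) and, for each, the death level is found by scanning candidate
#' levels from the birth level downwards until the superlevel-set component
#' containing the maximum also contains a strictly higher maximum (or an
#' equally high one further left, matching the elder-rule tie-break). Output
#' must equal [persistent_maxima()] exactly.
#'
#' @inheritParams persistent_maxima
#' @return Same contract as [persistent_maxima()].
#' @export
brute_force_maxima <- function(values, threshold = 0.04) {
  values <- check_profile(values)
  stopifnot(threshold >= 0)
  n <- length(values)

  r <- rle(values)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_max <- vapply(seq_len(k), function(t) {
    (t == 1L || r$values[t - 1L] < r$values[t]) &&
      (t == k || r$values[t + 1L] < r$values[t])
  }, logical(1))
  reps <- starts[is_max]

  lvls <- sort(unique(values), decreasing = TRUE)
  global_min <- min(values)

  rows <- lapply(reps, function(p) {
    b <- values[p]
    for (lv in lvls[lvls <= b]) {
      L <- p; while (L > 1L && values[L - 1L] >= lv) L <- L - 1L
      R <- p; while (R < n && values[R + 1L] >= lv) R <- R + 1L
      comp <- L:R
      elder <- values[comp] > b | (values[comp] == b & comp < p)
      if (any(elder)) {
        return(list(position = p, birth = b, death = lv, essential = FALSE))
      }
    }
    list(position = p, birth = b, death = global_min, essential = TRUE)
  })

  out <- persistence_frame(
    position = vapply(rows, `[[`, integer(1), "position"),
    birth = vapply(rows, `[[`, numeric(1), "birth"),
    death = vapply(rows, `[[`, numeric(1), "death"),
    essential = vapply(rows, `[[`, logical(1), "essential")
  )
  out <- out[out$essential | out$persistence >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
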
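`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible substream seed from a master seed
#'
#' All stochastic stages draw their seeds through named substreams of one
#' master seed, so adding or reordering a stage never perturbs the random
#' numbers any other stage sees.
#'
#' @param master integer master seed.
#' @param name character stream name (e.g. `"folds"`, `"permutations"`).
#' @param index optional integer index within the stream (e.g. a permutation
#'   or subsample number).
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
substream_seed <- function(master, name, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 131 + ch) %% m
  as.integer((h * 2654435 + (master %% m) * 97003 + index * 60013) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

abort_vagmet <- function(msg, class = "vagmet_error") {
  rlang::abort(msg, class = class)
}

check_unique <- function(x, what) {
  if (anyDuplicated(x)) {
    dup <- unique(x[duplicated(x)])
    abort_vagmet(sprintf(
      "duplicate %s: %s", what, paste(head(dup, 5L), collapse = ", ")
    ))
  }
  invisible(x)
}

# Solve the linear assignment problem (minimize total cost) for a small
# rectangular cost matrix via the O(n^3) augmenting-path (Jonker-Volgenant
# style) algorithm with row/column potentials. Returns, for each row, the
# assigned column index (NA for padded rows when nrow > ncol).
assignment_min <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  N <- max(n, m)
  a <- matrix(0, N, N)
  a[seq_len(n), seq_len(m)] <- cost
  u <- numeric(N + 1L)
  v <- numeric(N + 1L)
  p <- integer(N + 1L) # p[j+1]: row matched to column j (0 = none)
  way <- integer(N + 1L)
  for (i in seq_len(N)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, N)
    used <- rep(FALSE, N + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(N)) {
        if (!used[j + 1L]) {
          cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:N) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match_col <- rep(NA_integer_, n)
  for (j in seq_len(N)) {
    i <- p[j + 1L]
    if (i >= 1L && i <= n && j <= m) match_col[i] <- j
  }
  match_col
}

# Maximize total overlap on a contingency table: returns column assignment
# per row under the Hungarian method applied to -counts.
assignment_max <- function(counts) {
  assignment_min(max(counts) - counts)
}
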
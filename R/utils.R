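# internal helpers

# recursive merge: values in `user` override `base`; unknown names in
# `user` (absent from `base`) are an error when fail_closed = TRUE
deep_merge <- function(base, user, fail_closed = TRUE, path = character()) {
  if (!is.list(user) || !is.list(base) || is.null(names(user))) {
    return(user)
  }
  unknown <- setdiff(names(user), names(base))
  if (fail_closed && length(unknown) > 0) {
    stop("unknown field(s) in parameter file: ",
         paste(paste(c(path, unknown[1]), collapse = "$"), collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(user)) {
    if (nm %in% names(base) && is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- deep_merge(base[[nm]], user[[nm]], fail_closed, c(path, nm))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

# row-wise cumulative sums of a matrix via triangular matmul (fast for
# wide-but-short rows; avoids apply() over 1e5 rows per cycle)
row_cumsum <- function(m) {
  k <- ncol(m)
  m %*% upper.tri(diag(k), diag = TRUE)
}

# two independent RNG streams on top of base R's Mersenne Twister:
# the natural-history stream and the screening stream are advanced
# separately so that screening draws never perturb disease trajectories
# (common random numbers across strategies).
rng_streams <- function(seed) {
  seed <- as.integer(seed)
  make_state <- function(s) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(s)
    st <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    st
  }
  env <- new.env(parent = emptyenv())
  # offset keeps derived seeds well below 2^31
  env$states <- list(nh = make_state(seed),
                     screen = make_state((seed + 499979L) %% .Machine$integer.max))
  env
}

# draw n uniforms from one named stream, preserving the other streams
stream_runif <- function(streams, which, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", streams$states[[which]], globalenv())
  u <- stats::runif(n)
  streams$states[[which]] <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

stopifnot_scalar_prob <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1)) {
    stop(name, " must be a single probability in [0, 1]", call. = FALSE)
  }
}
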
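#' @importFrom rlang abort warn .data `%||%`
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols n count across
#' @importFrom stats median rnorm runif rbinom rgamma cor quantile sd setNames
#' @importFrom utils head tail
NULL

# Error helper: all user-input failures share a class so callers can condition
# on them.
stop_input <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "shapesorter_input_error")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` leaves the current stream in place.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_input("`seed` must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

BASES <- c("A", "C", "G", "T")
# For each reference base, the three substitution targets.
OTHER_BASES <- list(
  A = c("C", "G", "T"), C = c("A", "G", "T"),
  G = c("A", "C", "T"), T = c("A", "C", "G")
)

# Normalize an RNA/DNA sequence to uppercase DNA (U -> T) for read-level work.
normalize_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop_input("`sequence` must be a single string")
  }
  s <- chartr("u", "U", toupper(sequence))
  s <- chartr("U", "T", s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), BASES)
  if (length(bad) > 0) {
    stop_input("sequence contains non-ACGU/T characters: %s",
               paste(bad, collapse = ", "))
  }
  s
}

# DNA -> RNA alphabet for reporting.
to_rna <- function(x) chartr("T", "U", x)

phred_from_qual <- function(qual_chars) {
  if (length(qual_chars) == 1L) return(utf8ToInt(qual_chars) - 33L)
  # vector of single-character strings
  as.integer(unlist(lapply(qual_chars, utf8ToInt), use.names = FALSE)) - 33L
}
qual_char <- function(phred) intToUtf8(phred + 33L)

#' Parse a dot-bracket string into a base-pair partner vector
#'
#' Stack-matches `(` and `)` (pseudoknot-free). Position `i` pairs with
#' `partner[i]`; unpaired positions are `NA`.
#'
#' @param structure A dot-bracket string over `.`, `(`, `)`.
#' @return Integer vector of 1-based partner indices (`NA` = unpaired).
#' @examples
#' dotbracket_pairs("((..))")
#' @export
dotbracket_pairs <- function(structure) {
  if (!is.character(structure) || length(structure) != 1L || is.na(structure)) {
    stop_input("`structure` must be a single dot-bracket string")
  }
  chars <- strsplit(structure, "")[[1]]
  bad <- setdiff(unique(chars), c(".", "(", ")"))
  if (length(bad) > 0) {
    stop_input("invalid dot-bracket character(s): %s", paste(bad, collapse = ", "))
  }
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) {
        stop_input("unbalanced dot-bracket: unmatched ')' at position %d", i)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    }
  }
  if (length(stack) > 0) {
    stop_input("unbalanced dot-bracket: unmatched '(' at position %d",
               stack[length(stack)])
  }
  partner
}

#' Generate a random pseudoknot-free dot-bracket structure
#'
#' Walks left to right keeping a stack of open brackets; opens a new pair with
#' probability `pair_prob` when there is room to close it, closes an open pair
#' (respecting a minimum hairpin loop) otherwise, and emits dots elsewhere.
#' Useful for building synthetic structure ensembles and ground-truth profiles.
#'
#' @param length Structure length (nt).
#' @param pair_prob Probability of opening a pair when feasible.
#' @param min_loop Minimum unpaired nucleotides inside a hairpin loop.
#' @param seed Optional RNG seed (local to this call).
#' @return A dot-bracket string of the requested length.
#' @export
random_dotbracket <- function(length, pair_prob = 0.35, min_loop = 3, seed = NULL) {
  if (length < 1) stop_input("`length` must be positive")
  with_seed(seed, {
    chars <- character(length)
    stack <- integer(0)
    for (i in seq_len(length)) {
      remaining <- length - i + 1L
      must_close <- length(stack) >= remaining
      can_close <- length(stack) > 0 &&
        (i - stack[length(stack)] - 1L) >= min_loop
      can_open <- remaining >= length(stack) + min_loop + 2L
      if (must_close) {
        action <- "close"
      } else if (can_open && runif(1) < pair_prob) {
        action <- "open"
      } else if (can_close && runif(1) < 0.5) {
        action <- "close"
      } else {
        action <- "dot"
      }
      if (action == "open") {
        chars[i] <- "("
        stack <- c(stack, i)
      } else if (action == "close" && length(stack) > 0) {
        chars[i] <- ")"
        stack <- stack[-length(stack)]
      } else {
        chars[i] <- "."
      }
    }
    # close anything the walk left open (rare; forced closes handle most)
    out <- paste(chars, collapse = "")
    dotbracket_pairs(out)  # validates; forced closes guarantee balance
    out
  })
}

# Largest-remainder apportionment of `n` items into `fractions`.
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  sizes <- floor(exact)
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(exact - sizes, decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1L
  }
  as.integer(sizes)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
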
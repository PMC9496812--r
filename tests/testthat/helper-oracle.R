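# Brute-force matching oracle for the term-expression dialect, kept
# deliberately independent of the package's regex-based evaluator: bracket
# classes are fully expanded into literal alternatives and matching is a
# character-by-character scan (token-prefix containment), no regular
# expressions anywhere.

# Expand one expression token into its literal variants. A trailing "*"
# sets the wildcard flag instead of contributing characters. "[-]" expands
# to both "with hyphen" and "without hyphen".
oracle_expand_token <- function(tok) {
  tok <- tolower(gsub("['’]", "", tok))
  chars <- strsplit(tok, "")[[1]]
  variants <- ""
  wild <- FALSE
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      inner <- paste(chars[(i + 1):(j - 1)], collapse = "")
      opts <- strsplit(inner, ",", fixed = TRUE)[[1]]
      opts <- opts[nzchar(opts)]
      if (identical(opts, "-")) opts <- c("-", "")
      variants <- as.vector(outer(variants, opts, paste0))
      i <- j + 1L
    } else if (ch == "*" && i == length(chars)) {
      wild <- TRUE
      i <- i + 1L
    } else {
      variants <- paste0(variants, ch)
      i <- i + 1L
    }
  }
  list(variants = variants, wild = wild)
}

oracle_is_alnum <- function(ch) {
  nzchar(ch) && grepl("^[a-z0-9]$", ch)
}

# Match one fully-literal phrase (one variant per token) against prepared
# text by scanning every start position.
oracle_match_literal <- function(lits, wilds, text) {
  n <- nchar(text)
  tchars <- strsplit(text, "")[[1]]
  for (start in seq_len(max(n, 0))) {
    if (start > 1 && oracle_is_alnum(tchars[start - 1])) next
    pos <- start
    ok <- TRUE
    for (t in seq_along(lits)) {
      L <- nchar(lits[t])
      if (pos + L - 1 > n || substr(text, pos, pos + L - 1) != lits[t]) {
        ok <- FALSE
        break
      }
      pos <- pos + L
      if (wilds[t]) {
        while (pos <= n && oracle_is_alnum(tchars[pos])) pos <- pos + 1L
      }
      if (t < length(lits)) {
        if (pos > n || oracle_is_alnum(tchars[pos])) {
          ok <- FALSE
          break
        }
        while (pos <= n && !oracle_is_alnum(tchars[pos])) pos <- pos + 1L
      } else if (!wilds[t] && pos <= n && oracle_is_alnum(tchars[pos])) {
        ok <- FALSE
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

oracle_match_atom <- function(tokens, text) {
  per <- lapply(tokens, oracle_expand_token)
  wilds <- vapply(per, `[[`, logical(1), "wild")
  grids <- expand.grid(lapply(per, `[[`, "variants"),
                       stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grids))) {
    lits <- as.character(grids[r, ])
    if (oracle_match_literal(lits, wilds, text)) return(TRUE)
  }
  FALSE
}

oracle_eval_node <- function(node, text) {
  if (node$op == "atom") return(oracle_match_atom(node$tokens, text))
  hits <- vapply(node$args, oracle_eval_node, logical(1), text = text)
  if (node$op == "and") all(hits) else any(hits)
}

# Oracle verdict for an expression source string against raw text.
oracle_matches <- function(expression_text, text) {
  ast <- parse_term_expression(expression_text)$ast
  prepped <- tolower(gsub("['’]", "", text))
  oracle_eval_node(ast, prepped)
}

# Random expression source over a small alphabet: atoms with optional
# trailing wildcards and bracket classes, joined by and/or with
# occasional parenthesised groups.
random_token <- function() {
  len <- sample(1:4, 1)
  chars <- sample(c("a", "b", "c", "d"), len, replace = TRUE)
  if (stats::runif(1) < 0.25) {
    pos <- sample(len, 1)
    chars[pos] <- paste0("[", paste(sample(c("a", "b", "c", "d"),
                                           sample(2:3, 1)), collapse = ","),
                         "]")
  }
  tok <- paste(chars, collapse = "")
  if (stats::runif(1) < 0.15) tok <- paste0(tok, "[-]", sample(c("a", "b"), 1))
  if (stats::runif(1) < 0.3) tok <- paste0(tok, "*")
  tok
}

random_atom <- function() {
  paste(replicate(sample(1:2, 1, prob = c(0.8, 0.2)), random_token()),
        collapse = " ")
}

random_expression <- function() {
  n <- sample(1:3, 1)
  parts <- replicate(n, {
    if (stats::runif(1) < 0.2) {
      paste0("(", paste(replicate(2, random_atom()), collapse = " or "), ")")
    } else {
      random_atom()
    }
  })
  ops <- sample(c(" or ", " and "), max(n - 1, 0), replace = TRUE)
  out <- parts[1]
  for (i in seq_along(ops)) out <- paste0(out, ops[i], parts[i + 1])
  out
}

random_corpus_string <- function() {
  n <- sample(1:5, 1)
  toks <- replicate(n, paste(sample(c("a", "b", "c", "d", "ab", "abc",
                                      "bc", "cd", "a-b", "dd"),
                                    1), collapse = ""))
  seps <- sample(c(" ", "-", ", ", "'s "), n, replace = TRUE)
  paste0(paste0(toks, c(seps[-n], "")), collapse = "")
}
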
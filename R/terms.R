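# The term-expression dialect used by the named inclusion/exclusion
# criteria, e.g.
#
#   Family and (Med* or Clinic or Centre or Center or Associate* or Care or Practice)
#   Wom[a,e]n* or Menopause or Matern* or Birth* or Obstetric* or Gyne*
#
# Semantics:
#   *        any characters may follow on that token (prefix match)
#   [a,e]    exactly one of the listed characters at that position
#   [-]      an optional hyphen (strict mode: a literal hyphen)
#   ( ... )  grouping; "or" / "and" combinators, "or" binds looser
#   consecutive bare tokens form a phrase that must appear contiguously
#
# Matching is case-insensitive; apostrophes/possessives are stripped from
# the text first ("Women's" -> "Womens"); every atom must start at a word
# boundary, and without a trailing * must also end at one. Criteria are
# evaluated against the concatenation of an address's embedded facility
# label and street lines only — never city or postal code, so that city
# names cannot misfire.

expr_keywords <- c("and", "or")

tokenize_expression <- function(text) {
  t <- gsub("\\(", " ( ", text)
  t <- gsub("\\)", " ) ", t)
  toks <- strsplit(trimws(t), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a term expression
#'
#' @param text the expression source, e.g. `"Wom[a,e]n* or Matern*"`.
#' @return a `term_expression` object (boolean AST over phrase atoms).
#' @export
parse_term_expression <- function(text) {
  if (!nzchar(trimws(text))) {
    stop("parse error: empty term expression", call. = FALSE)
  }
  check_brackets(text)
  toks <- tokenize_expression(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("parse error: unexpected token '", st$toks[st$pos],
         "' at position ", st$pos, call. = FALSE)
  }
  structure(list(source_text = text, ast = ast), class = "term_expression")
}

check_brackets <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth_sq <- 0L; depth_rd <- 0L
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == "[") depth_sq <- depth_sq + 1L
    if (c == "]") depth_sq <- depth_sq - 1L
    if (c == "(") depth_rd <- depth_rd + 1L
    if (c == ")") depth_rd <- depth_rd - 1L
    if (depth_sq < 0L || depth_rd < 0L || depth_sq > 1L) {
      stop("parse error: unbalanced bracket at position ", i, call. = FALSE)
    }
  }
  if (depth_sq != 0L || depth_rd != 0L) {
    stop("parse error: unbalanced bracket at position ", nchar(text),
         call. = FALSE)
  }
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA
advance <- function(st) st$pos <- st$pos + 1L
is_kw <- function(tok, kw) !is.na(tok) && tolower(tok) == kw

parse_or <- function(st) {
  args <- list(parse_and(st))
  while (is_kw(peek(st), "or")) {
    advance(st)
    args[[length(args) + 1L]] <- parse_and(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

parse_and <- function(st) {
  args <- list(parse_factor(st))
  while (is_kw(peek(st), "and")) {
    advance(st)
    args[[length(args) + 1L]] <- parse_factor(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

parse_factor <- function(st) {
  tok <- peek(st)
  if (is.na(tok)) stop("parse error: unexpected end of expression", call. = FALSE)
  if (tok == "(") {
    advance(st)
    node <- parse_or(st)
    if (!identical(peek(st), ")")) {
      stop("parse error: expected ')' at position ", st$pos, call. = FALSE)
    }
    advance(st)
    return(node)
  }
  if (tok == ")" || tolower(tok) %in% expr_keywords) {
    stop("parse error: unexpected token '", tok, "' at position ", st$pos,
         call. = FALSE)
  }
  phrase <- character()
  while (!is.na(tok <- peek(st)) && tok != "(" && tok != ")" &&
         !(tolower(tok) %in% expr_keywords)) {
    phrase <- c(phrase, tok)
    advance(st)
  }
  list(op = "atom", tokens = phrase, source = paste(phrase, collapse = " "))
}

#' Render a term expression back to source text
#'
#' Rendering then re-parsing yields an identical tree.
#'
#' @param x a `term_expression` or AST node.
#' @return character scalar.
#' @export
render_term_expression <- function(x) {
  node <- if (inherits(x, "term_expression")) x$ast else x
  render_node(node, parent = "top")
}

render_node <- function(node, parent) {
  if (node$op == "atom") return(node$source)
  sep <- if (node$op == "or") " or " else " and "
  inner <- vapply(node$args, render_node, character(1), parent = node$op)
  s <- paste(inner, collapse = sep)
  # "or" under "and" needs parentheses; atoms and "and" under "or" do not
  if (node$op == "or" && parent == "and") paste0("(", s, ")") else s
}

# --- compilation to anchored PCRE ---------------------------------------

# One expression token -> regex fragment + wildcard flag.
compile_token <- function(tok, strict_hyphen = FALSE) {
  tok <- tolower(gsub("['’]", "", tok))
  chars <- strsplit(tok, "")[[1]]
  frag <- character()
  wildcard <- FALSE
  i <- 1L
  while (i <= length(chars)) {
    c <- chars[i]
    if (c == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) {
        stop("parse error: unbalanced bracket in token '", tok,
             "' at position ", i, call. = FALSE)
      }
      inner <- paste(chars[(i + 1):(j - 1)], collapse = "")
      opts <- strsplit(inner, ",", fixed = TRUE)[[1]]
      opts <- opts[nzchar(opts)]
      if (identical(opts, "-") || (length(opts) == 0 && grepl("-", inner))) {
        frag <- c(frag, if (strict_hyphen) "\\-" else "-?")
      } else {
        esc <- vapply(opts, function(o) {
          if (o %in% c("^", "]", "\\", "-")) paste0("\\", o) else o
        }, character(1))
        frag <- c(frag, paste0("[", paste(esc, collapse = ""), "]"))
      }
      i <- j + 1L
    } else if (c == "*") {
      if (i == length(chars)) {
        wildcard <- TRUE
      } else {
        frag <- c(frag, "[a-z0-9]*")
      }
      i <- i + 1L
    } else {
      specials <- c(".", "\\", "+", "?", "[", "]", "^", "$", "(", ")",
                    "{", "}", "|", "-")
      frag <- c(frag, if (c %in% specials) paste0("\\", c) else c)
      i <- i + 1L
    }
  }
  list(regex = paste(frag, collapse = ""), wildcard = wildcard)
}

# A phrase atom -> one anchored regex. Tokens are separated by one or more
# non-word characters; a trailing * drops the end-of-token anchor.
compile_atom <- function(tokens, strict_hyphen = FALSE) {
  parts <- lapply(tokens, compile_token, strict_hyphen = strict_hyphen)
  frags <- vapply(parts, `[[`, character(1), "regex")
  mids <- vapply(parts[-length(parts)], function(p) {
    if (p$wildcard) "[a-z0-9]*[^a-z0-9]+" else "[^a-z0-9]+"
  }, character(1))
  body <- frags[1]
  if (length(frags) > 1) {
    body <- paste0(frags[1],
                   paste0(mids, frags[-1], collapse = ""))
  }
  last_wild <- parts[[length(parts)]]$wildcard
  paste0("(?<![a-z0-9])", body, if (!last_wild) "(?![a-z0-9])")
}

#' Prepare free text for term matching
#'
#' Lower-cases and strips apostrophes/possessive marks; all other
#' punctuation is preserved (token separators are handled by the matcher).
#'
#' @param text character vector.
#' @return character vector.
#' @export
prepare_match_text <- function(text) {
  gsub("['’]", "", tolower(text))
}

#' A named inclusion/exclusion criterion
#'
#' @param name the criterion's working-list name.
#' @param polarity `"include"` or `"exclude"`.
#' @param expressions character vector of term expressions (may be empty:
#'   the walk-in and urgent-and-primary-care criteria are driven purely by
#'   their partial lists).
#' @param name_list literal facility names (the clinic-specific
#'   substitutions), matched case-insensitively as whole phrases.
#' @param strict_hyphen match `[-]` as a literal hyphen instead of an
#'   optional one.
#' @return a `term_criterion` object with pre-compiled matchers.
#' @export
term_criterion <- function(name, polarity = c("include", "exclude"),
                           expressions = character(),
                           name_list = character(),
                           strict_hyphen = FALSE) {
  polarity <- match.arg(polarity)
  parsed <- lapply(expressions, function(e) {
    ex <- parse_term_expression(e)
    ex$ast <- precompile_node(ex$ast, strict_hyphen)
    ex
  })
  structure(list(name = name, polarity = polarity, expressions = parsed,
                 name_list = name_list, strict_hyphen = strict_hyphen),
            class = "term_criterion")
}

# Attach compiled regexes to atoms once, at criterion construction time.
precompile_node <- function(node, strict_hyphen) {
  if (node$op == "atom") {
    node$regex <- compile_atom(node$tokens, strict_hyphen)
    return(node)
  }
  node$args <- lapply(node$args, precompile_node, strict_hyphen = strict_hyphen)
  node
}

eval_node <- function(node, text_prep, strict_hyphen, fired) {
  if (node$op == "atom") {
    rx <- node$regex %||% compile_atom(node$tokens, strict_hyphen)
    m <- regexpr(rx, text_prep, perl = TRUE)
    hit <- m[1] > 0
    if (hit) {
      fired[[length(fired) + 1L]] <- data.frame(
        atom = node$source,
        span = substr(text_prep, m[1], m[1] + attr(m, "match.length") - 1),
        stringsAsFactors = FALSE)
    }
    return(list(matched = hit, fired = fired))
  }
  hits <- logical(length(node$args))
  for (i in seq_along(node$args)) {
    r <- eval_node(node$args[[i]], text_prep, strict_hyphen, fired)
    hits[i] <- r$matched
    fired <- r$fired
  }
  list(matched = if (node$op == "and") all(hits) else any(hits),
       fired = fired)
}

#' Evaluate a criterion against free text
#'
#' Pure and deterministic: the result depends only on the criterion and
#' the text. The audit trail (`fired_atoms`) is non-empty whenever the
#' criterion matched.
#'
#' @param criterion a [term_criterion()].
#' @param text the text to test (facility label + street lines).
#' @return list `matched` (logical) and `fired_atoms` (data.frame with
#'   columns `criterion`, `atom`, `span`).
#' @export
evaluate_criterion <- function(criterion, text) {
  no_fire <- data.frame(criterion = character(), atom = character(),
                        span = character(), stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) {
    return(list(matched = FALSE, fired_atoms = no_fire))
  }
  tp <- prepare_match_text(text)
  matched <- FALSE
  fired <- list()
  for (ex in criterion$expressions) {
    r <- eval_node(ex$ast, tp, criterion$strict_hyphen, fired)
    fired <- r$fired
    matched <- matched || r$matched
  }
  for (nm in criterion$name_list) {
    nm_toks <- strsplit(prepare_match_text(nm), "[^a-z0-9]+")[[1]]
    nm_toks <- nm_toks[nzchar(nm_toks)]
    if (!length(nm_toks)) next
    rx <- paste0("(?<![a-z0-9])", paste(nm_toks, collapse = "[^a-z0-9]+"),
                 "(?![a-z0-9])")
    m <- regexpr(rx, tp, perl = TRUE)
    if (m[1] > 0) {
      matched <- TRUE
      fired[[length(fired) + 1L]] <- data.frame(
        atom = paste0("{", nm, "}"),
        span = substr(tp, m[1], m[1] + attr(m, "match.length") - 1),
        stringsAsFactors = FALSE)
    }
  }
  fa <- if (length(fired)) do.call(rbind, fired) else
    data.frame(atom = character(), span = character(), stringsAsFactors = FALSE)
  if (nrow(fa)) fa <- cbind(criterion = criterion$name, fa)
  else fa <- no_fire
  list(matched = matched, fired_atoms = fa)
}

#' The default named criteria
#'
#' Five inclusion and seven exclusion criteria. The walk-in and urgent-and-
#' primary-care criteria carry no expressions (their working lists are
#' filled from the corresponding partial lists); the hospital, long-term
#' care and corrections criteria carry both a partial list and fallback
#' terms.
#'
#' @param name_lists optional named list of literal facility-name vectors
#'   keyed by criterion name (the clinic-specific substitutions for
#'   first-nations, sexual-health and virtual criteria).
#' @param strict_hyphen match `[-]` literally.
#' @return named list of [term_criterion()] objects, in definition order.
#' @export
default_criteria <- function(name_lists = list(), strict_hyphen = FALSE) {
  nl <- function(n) name_lists[[n]] %||% character()
  crits <- list(
    term_criterion("walk_in", "include", character(), nl("walk_in"), strict_hyphen),
    term_criterion("upcc", "include", character(), nl("upcc"), strict_hyphen),
    term_criterion("family", "include",
      "Family and (Med* or Clinic or Centre or Center or Associate* or Care or Practice)",
      nl("family"), strict_hyphen),
    term_criterion("first_nations", "include",
      "First Nation* or First People* or Native or Aboriginal or Indigenous",
      nl("first_nations"), strict_hyphen),
    term_criterion("clinic_center", "include",
      "Clinic* or Associate* or Center or Centre of Practice or Doctor*",
      nl("clinic_center"), strict_hyphen),
    term_criterion("hospital", "exclude", "Hosp*", nl("hospital"), strict_hyphen),
    term_criterion("long_term_care", "exclude",
      "Lodging or Lodge* or Manor or Senior or ALC",
      nl("long_term_care"), strict_hyphen),
    term_criterion("corrections", "exclude",
      "Correction* or Immigra* or Pretrial or Custody or Institution or Detention or Holding or Healing Village",
      nl("corrections"), strict_hyphen),
    term_criterion("sexual_health", "exclude",
      "Sexual or STI or STD", nl("sexual_health"), strict_hyphen),
    term_criterion("womens_health", "exclude",
      "Wom[a,e]n* or Menopause or Matern* or Birth* or Obstetric* or Gyne*",
      nl("womens_health"), strict_hyphen),
    term_criterion("virtual", "exclude",
      "Virtual or E[-]Health or Tele* or I[-]Health",
      nl("virtual"), strict_hyphen),
    term_criterion("administrative", "exclude",
      "Airport or Consulting or Admin* or Fraser Health Authority or First Nation* Health Authority or Coroner or CPSBC or College of Physician* and Surgeon* or Health Canada or VCH or Worksafe or Worksafebc or Worker* Comp* or BCAA or Veteran* Affair or RCMP or Air Canada or Quality",
      nl("administrative"), strict_hyphen)
  )
  stats::setNames(crits, vapply(crits, `[[`, character(1), "name"))
}

#' Names of criteria that carry term expressions
#' @param criteria output of [default_criteria()].
#' @return character vector.
#' @export
term_bearing_criteria <- function(criteria = default_criteria()) {
  names(criteria)[vapply(criteria, function(cr)
    length(cr$expressions) > 0 || length(cr$name_list) > 0, logical(1))]
}
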
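#' Declare the keyword list of a search filter
#'
#' @param term Character vector of keyword surface forms.
#' @param category Category label per keyword (recycled), e.g. `"device"`,
#'   `"brand"`, `"behavior"`.
#' @param mode Match mode per keyword (recycled): `"word"` (whole-word,
#'   case-insensitive), `"phrase"` (exact word sequence), `"hashtag"`
#'   (matches with or without the leading `#`), or `"handle"` (matches
#'   messages authored by or mentioning the account).
#' @return A tibble with columns `term`, `category`, `mode`.
#' @examples
#' filter_keywords(c("vape", "e-cig", "@blucigs"),
#'                 category = c("behavior", "device", "brand"),
#'                 mode = c("word", "word", "handle"))
#' @export
filter_keywords <- function(term, category = "general", mode = "word") {
  if (length(term) == 0L) {
    # an empty keyword set is legal: the filter retrieves nothing
    return(tibble(term = character(), category = character(),
                  mode = character()))
  }
  if (any(is.na(term)) || any(!nzchar(term))) {
    abort("Every keyword needs a non-empty surface form.")
  }
  mode <- rep_len(mode, length(term))
  bad_mode <- setdiff(unique(mode), c("word", "phrase", "hashtag", "handle"))
  if (length(bad_mode) > 0L) {
    abort(paste0("Unknown match mode: ", paste(bad_mode, collapse = ", "), "."))
  }
  no_sigil <- mode == "handle" & !startsWith(term, "@")
  if (any(no_sigil)) {
    abort(paste0(
      "Handle-mode keywords must start with '@': ",
      paste(term[no_sigil], collapse = ", "), "."
    ))
  }
  tibble(
    term = as.character(term),
    category = rep_len(as.character(category), length(term)),
    mode = mode
  )
}

#' Define a boolean keyword search filter
#'
#' A search filter combines a keyword list with boolean search rules.
#' Without a `rule`, a message is retrieved when any non-handle keyword
#' matches (OR over the list). A `rule` restricts retrieval to a boolean
#' expression over keyword presence, written with `AND`, `OR`, `NOT` and
#' parentheses, quoting multi-word terms: e.g.
#' `'(vape OR "e-cig") AND NOT cigar'`. `exclusions` are co-occurrence
#' vetoes: a message containing both terms of a pair is dropped (the
#' classic example vetoes "atomizer" co-occurring with "perfume", which
#' signals perfume bottles, not vaping devices). Handle-mode keywords
#' retrieve messages authored by or mentioning the account regardless of
#' terms and vetoes.
#'
#' @param keywords A keyword tibble from [filter_keywords()].
#' @param rule Optional boolean rule string over declared keyword terms.
#' @param exclusions Optional list of length-2 character vectors, each a
#'   co-occurrence veto pair of declared terms.
#' @return An object of class `search_filter`.
#' @export
search_filter <- function(keywords, rule = NULL, exclusions = NULL) {
  if (!is.data.frame(keywords) ||
      !all(c("term", "category", "mode") %in% names(keywords))) {
    abort("`keywords` must come from `filter_keywords()`.")
  }
  keywords <- as_tibble(keywords)
  if (anyDuplicated(tolower(keywords$term))) {
    abort("Keyword terms must be unique (case-insensitive).")
  }
  ast <- NULL
  if (!is.null(rule)) {
    if (!is.character(rule) || length(rule) != 1L || !nzchar(rule)) {
      abort("`rule` must be a single non-empty string.")
    }
    ast <- parse_rule(rule)
    undeclared <- setdiff(rule_leaves(ast), tolower(keywords$term))
    if (length(undeclared) > 0L) {
      abort(paste0(
        "Rule references undeclared keyword(s): ",
        paste(undeclared, collapse = ", "), "."
      ))
    }
  }
  if (!is.null(exclusions)) {
    if (!is.list(exclusions) ||
        !all(vapply(exclusions, function(p) length(p) == 2L, logical(1)))) {
      abort("`exclusions` must be a list of term pairs.")
    }
    ex_terms <- tolower(unlist(exclusions))
    undeclared <- setdiff(ex_terms, tolower(keywords$term))
    if (length(undeclared) > 0L) {
      abort(paste0(
        "Exclusion references undeclared keyword(s): ",
        paste(undeclared, collapse = ", "), "."
      ))
    }
  }
  structure(
    list(keywords = keywords, rule = rule, rule_ast = ast,
         exclusions = exclusions),
    class = "search_filter"
  )
}

#' @export
print.search_filter <- function(x, ...) {
  cat(sprintf(
    "<search_filter> %d keywords (%s)\n", nrow(x$keywords),
    paste(sprintf("%s: %d", names(table(x$keywords$category)),
                  as.integer(table(x$keywords$category))), collapse = ", ")
  ))
  if (!is.null(x$rule)) cat("  rule:", x$rule, "\n")
  if (!is.null(x$exclusions)) {
    cat("  exclusions:",
        paste(vapply(x$exclusions, paste, character(1), collapse = " + "),
              collapse = "; "), "\n")
  }
  invisible(x)
}

# boolean rule parser --------------------------------------------------------
# grammar: expr := term (OR term)* ; term := factor (AND factor)* ;
#          factor := NOT factor | '(' expr ')' | leaf

tokenize_rule <- function(rule) {
  pat <- '"[^"]*"|\\(|\\)|[^\\s()]+'
  toks <- regmatches(rule, gregexpr(pat, rule, perl = TRUE))[[1L]]
  if (length(toks) == 0L) abort("Empty rule.")
  toks
}

parse_rule <- function(rule) {
  toks <- tokenize_rule(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  fail <- function(msg) {
    abort(sprintf("Rule parse error near token %d ('%s'): %s",
                  pos, peek() %||% "<end>", msg))
  }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && toupper(peek()) == "OR") {
      advance()
      node <- list(op = "or", lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && toupper(peek()) == "AND") {
      advance()
      node <- list(op = "and", lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("expected a keyword, NOT, or '('")
    if (toupper(t) == "NOT") {
      advance()
      return(list(op = "not", arg = parse_factor()))
    }
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      advance()
      return(node)
    }
    if (t == ")" || toupper(t) %in% c("AND", "OR")) {
      fail("expected a keyword, NOT, or '('")
    }
    advance()
    list(op = "leaf", term = tolower(gsub('^"|"$', "", t)))
  }
  ast <- parse_expr()
  if (!is.na(peek())) fail("unexpected trailing input")
  ast
}

rule_leaves <- function(ast) {
  if (ast$op == "leaf") return(ast$term)
  if (ast$op == "not") return(rule_leaves(ast$arg))
  unique(c(rule_leaves(ast$lhs), rule_leaves(ast$rhs)))
}

eval_rule <- function(ast, match_matrix) {
  switch(ast$op,
    leaf = match_matrix[, ast$term],
    not = !eval_rule(ast$arg, match_matrix),
    and = eval_rule(ast$lhs, match_matrix) & eval_rule(ast$rhs, match_matrix),
    or = eval_rule(ast$lhs, match_matrix) | eval_rule(ast$rhs, match_matrix)
  )
}

# matching -------------------------------------------------------------------

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# boundary that treats letters, digits and underscore as word characters;
# keywords like "e-cig" or "#ecig" need boundaries beyond regex \b
bounded <- function(core) {
  paste0("(?<![\\p{L}\\p{N}_])", core, "(?![\\p{L}\\p{N}_])")
}

keyword_regex <- function(term, mode) {
  t <- tolower(term)
  switch(mode,
    word = bounded(escape_regex(t)),
    phrase = bounded(gsub("\\s+", "\\\\s+", escape_regex(t))),
    hashtag = bounded(paste0("#?", escape_regex(sub("^#", "", t)))),
    handle = bounded(escape_regex(t)) # '@name' mention in text
  )
}

#' Compile a search filter into a deterministic matcher
#'
#' Precompiles one regular expression per keyword and binds the boolean
#' rule, veto pairs and handle rules. Compiling separately from applying
#' lets one filter run over many corpora.
#'
#' @param filter A [search_filter()].
#' @return An object of class `compiled_filter`.
#' @export
compile_filter <- function(filter) {
  if (!inherits(filter, "search_filter")) {
    abort("`filter` must be a `search_filter`.")
  }
  kw <- filter$keywords
  structure(
    list(
      filter = filter,
      terms = tolower(kw$term),
      regex = vapply(seq_len(nrow(kw)), function(i) {
        keyword_regex(kw$term[[i]], kw$mode[[i]])
      }, character(1)),
      is_handle = kw$mode == "handle",
      handle_names = tolower(sub("^@", "", kw$term[kw$mode == "handle"]))
    ),
    class = "compiled_filter"
  )
}

#' Partition a corpus into retrieved and unretrieved messages
#'
#' Applies a compiled (or plain) search filter to a message corpus and
#' returns the corpus with a retrieval flag and per-message provenance:
#' which keywords matched, and whether a veto or handle rule fired. The
#' partition is exhaustive, disjoint, and deterministic. Records with a
#' missing or empty `text` cannot be matched; they are dropped with a
#' warning and counted in the `n_malformed` attribute.
#'
#' @param corpus A data frame with at least `id` and `text`; `author`
#'   is used by handle rules when present.
#' @param filter A [search_filter()] or [compile_filter()] result.
#' @return The corpus as a tibble with added columns `retrieved`
#'   (logical), `matched_terms` (comma-separated matching keywords) and
#'   `provenance` (`"rule"`, `"handle"`, `"excluded"` or `""`).
#' @examples
#' corpus <- tibble::tibble(
#'   id = c("1", "2"), text = c("loving my new vape pen", "pass the salt"),
#'   author = c("u1", "u2")
#' )
#' apply_filter(corpus, search_filter(filter_keywords("vape")))
#' @export
apply_filter <- function(corpus, filter) {
  if (inherits(filter, "search_filter")) filter <- compile_filter(filter)
  if (!inherits(filter, "compiled_filter")) {
    abort("`filter` must be a `search_filter` or `compiled_filter`.")
  }
  if (!is.data.frame(corpus) || !all(c("id", "text") %in% names(corpus))) {
    abort("`corpus` must be a data frame with `id` and `text` columns.")
  }
  corpus <- as_tibble(corpus)
  if (anyDuplicated(corpus$id[!is.na(corpus$id)])) {
    abort("Message ids must be unique within a corpus.")
  }
  ok <- !is.na(corpus$id) & !is.na(corpus$text) & nzchar(corpus$text)
  n_malformed <- sum(!ok)
  if (n_malformed > 0L) {
    warn(sprintf("Skipped %d malformed record(s) with missing id or text.",
                 n_malformed))
    corpus <- corpus[ok, , drop = FALSE]
  }
  n_msg <- nrow(corpus)
  text_lc <- tolower(corpus$text)

  terms <- filter$terms
  if (length(terms) == 0L || n_msg == 0L) {
    out <- dplyr::mutate(
      corpus, retrieved = FALSE,
      matched_terms = character(n_msg), provenance = character(n_msg)
    )
    attr(out, "n_malformed") <- n_malformed
    return(out)
  }

  mm <- matrix(FALSE, n_msg, length(terms),
               dimnames = list(NULL, terms))
  for (j in seq_along(terms)) {
    mm[, j] <- grepl(filter$regex[[j]], text_lc, perl = TRUE)
  }
  # handle keywords also match on the author field
  if (any(filter$is_handle) && "author" %in% names(corpus)) {
    authors <- tolower(sub("^@", "", corpus$author))
    for (j in which(filter$is_handle)) {
      mm[, j] <- mm[, j] |
        (!is.na(authors) & authors == sub("^@", "", terms[[j]]))
    }
  }

  base <- if (!is.null(filter$filter$rule_ast)) {
    eval_rule(filter$filter$rule_ast, mm)
  } else if (any(!filter$is_handle)) {
    rowSums(mm[, !filter$is_handle, drop = FALSE]) > 0L
  } else {
    rep(FALSE, n_msg)
  }
  vetoed <- rep(FALSE, n_msg)
  for (pair in filter$filter$exclusions %||% list()) {
    vetoed <- vetoed | (mm[, tolower(pair[[1L]])] & mm[, tolower(pair[[2L]])])
  }
  handle_hit <- if (any(filter$is_handle)) {
    rowSums(mm[, filter$is_handle, drop = FALSE]) > 0L
  } else {
    rep(FALSE, n_msg)
  }
  retrieved <- (base & !vetoed) | handle_hit

  matched <- vapply(seq_len(n_msg), function(i) {
    paste(terms[mm[i, ]], collapse = ",")
  }, character(1))
  provenance <- dplyr::case_when(
    handle_hit ~ "handle",
    base & vetoed ~ "excluded",
    retrieved ~ "rule",
    .default = ""
  )
  out <- dplyr::mutate(
    corpus, retrieved = retrieved,
    matched_terms = matched, provenance = provenance
  )
  attr(out, "n_malformed") <- n_malformed
  out
}
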
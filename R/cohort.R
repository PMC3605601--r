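#' Index vectors: secret-shared cohort membership
#'
#' A cohort (case or control group) is a secret-shared zero-one vector with one
#' entry per donor column; entry `i` reconstructs to 1 iff donor `i` belongs to
#' the group. In scenario 1 the analyst knows the member list and shares it
#' directly; in scenario 2 membership is evaluated obliviously from shared
#' phenotypes (see [evaluate_criterion()]).
#'
#' @param member_ids Donor IDs of the group (must be a subset of `donor_ids`).
#' @param donor_ids All donor IDs, in database column order.
#' @param session An [mpc_session()].
#' @return A bit-valued `shared_vector` of length `length(donor_ids)`.
#' @export
index_from_plaintext <- function(member_ids, donor_ids, session) {
  unknown <- setdiff(member_ids, donor_ids)
  if (length(unknown) > 0)
    stop(sprintf("unknown member ID(s): %s",
                 paste(utils::head(unknown, 3), collapse = ", ")))
  share_secret(as.integer(donor_ids %in% member_ids), session, bit = TRUE)
}

#' Complement of an index vector
#'
#' Entrywise `1 - x_i` (local operation); with the original vector it
#' partitions the donor columns, which is how a control group is formed as
#' "everyone not in the case group".
#'
#' @param v A bit-valued `shared_vector`.
#' @return A bit-valued `shared_vector`.
#' @export
complement <- function(v) {
  out <- add_public(neg_shared(v), 1)
  out$bit <- TRUE
  out
}

# ---------------------------------------------------------------------------
# Inclusion-criterion mini-language (grammar v1):
#   expr    := or
#   or      := and ( ('|' | 'or')  and )*
#   and     := not ( ('&' | 'and') not )*
#   not     := ('!' | 'not') not | primary
#   primary := '(' expr ')' | attr op integer | attr
#   op      := '<' | '<=' | '==' | '=' | '>=' | '>'
# Bare attributes must be boolean; comparisons need integer attributes.
# ---------------------------------------------------------------------------

#' Parse an inclusion criterion
#'
#' Parses expressions such as `"age >= 50 & has_diabetes"` into an expression
#' tree over phenotype attributes. Leaves are boolean attributes or comparisons
#' of an integer attribute against a public constant; internal nodes are
#' AND / OR / NOT.
#'
#' @param text Criterion string (grammar v1, see Details).
#' @return A `criterion` object (expression tree).
#' @export
parse_criterion <- function(text) {
  tokens <- criterion_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- tokens
  st$pos <- 1L
  tree <- crit_or(st)
  if (st$pos <= length(st$toks))
    stop(sprintf("criterion parse error: unexpected '%s'", st$toks[st$pos]))
  structure(list(tree = tree, text = text, grammar = "v1"),
            class = "criterion")
}

criterion_tokens <- function(text) {
  pat <- "\\(|\\)|<=|>=|==|=|<|>|&&?|\\|\\|?|!|[A-Za-z_][A-Za-z0-9_]*|[0-9]+"
  m <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  rest <- gsub("[ \t]", "", gsub(pat, "", text))
  if (nchar(rest) > 0)
    stop(sprintf("criterion parse error: unrecognized characters '%s'", rest))
  toks
}

crit_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else ""
crit_take <- function(st) { t <- crit_peek(st); st$pos <- st$pos + 1L; t }

crit_or <- function(st) {
  left <- crit_and(st)
  while (crit_peek(st) %in% c("|", "||", "or")) {
    crit_take(st)
    left <- list(op = "or", args = list(left, crit_and(st)))
  }
  left
}

crit_and <- function(st) {
  left <- crit_not(st)
  while (crit_peek(st) %in% c("&", "&&", "and")) {
    crit_take(st)
    left <- list(op = "and", args = list(left, crit_not(st)))
  }
  left
}

crit_not <- function(st) {
  if (crit_peek(st) %in% c("!", "not")) {
    crit_take(st)
    return(list(op = "not", args = list(crit_not(st))))
  }
  crit_primary(st)
}

crit_primary <- function(st) {
  t <- crit_peek(st)
  if (t == "(") {
    crit_take(st)
    e <- crit_or(st)
    if (crit_take(st) != ")") stop("criterion parse error: expected ')'")
    return(e)
  }
  if (!grepl("^[A-Za-z_]", t))
    stop(sprintf("criterion parse error: expected attribute, got '%s'", t))
  attr <- crit_take(st)
  nxt <- crit_peek(st)
  if (nxt %in% c("<", "<=", "=", "==", ">=", ">")) {
    op <- crit_take(st)
    cv <- crit_take(st)
    if (!grepl("^[0-9]+$", cv))
      stop("criterion parse error: comparison needs an integer constant")
    if (op == "=") op <- "=="
    return(list(op = "cmp", cmp = op, attr = attr, const = as.numeric(cv)))
  }
  list(op = "leaf", attr = attr)
}

#' @export
print.criterion <- function(x, ...) {
  cat(sprintf("<criterion v1> %s\n", x$text))
  invisible(x)
}

#' Evaluate an inclusion criterion obliviously
#'
#' The hosts evaluate the criterion on the shared phenotype database and output
#' the membership bits in secret-shared form: boolean leaves are the shared
#' attribute itself, integer comparisons go through the secure comparison
#' protocol (the public constant is shared trivially, and equality is
#' `(a >= b)*(b >= a)`), AND is a secure multiplication, OR is
#' `1 - (1-a)(1-b)` and NOT is `1 - a`. The number of secure operations depends
#' only on the criterion shape and the donor count, never on the data.
#'
#' @param db A `shared_phenotype_db`.
#' @param criterion A [parse_criterion()] result or a criterion string.
#' @param session An [mpc_session()].
#' @return A bit-valued `shared_vector` (index vector).
#' @export
evaluate_criterion <- function(db, criterion, session) {
  if (is.character(criterion)) criterion <- parse_criterion(criterion)
  out <- crit_eval(criterion$tree, db, session)
  out$bit <- TRUE
  out
}

crit_eval <- function(node, db, session) {
  get_attr <- function(nm) {
    a <- db$attributes[[nm]]
    if (is.null(a)) stop(sprintf("schema mismatch: no attribute '%s'", nm))
    a
  }
  switch(node$op,
    leaf = {
      a <- get_attr(node$attr)
      if (!isTRUE(a$bit))
        stop(sprintf("schema mismatch: '%s' is not boolean", node$attr))
      a
    },
    cmp = {
      a <- get_attr(node$attr)
      cst <- shared_constant(rep(node$const, a$n), session)
      switch(node$cmp,
        ">=" = secure_geq(a, cst, session),
        "<=" = secure_geq(cst, a, session),
        "<"  = complement(secure_geq(a, cst, session)),
        ">"  = complement(secure_geq(cst, a, session)),
        "==" = mul_shared(secure_geq(a, cst, session),
                          secure_geq(cst, a, session), session))
    },
    and = mul_shared(crit_eval(node$args[[1]], db, session),
                     crit_eval(node$args[[2]], db, session), session),
    or = {
      a <- crit_eval(node$args[[1]], db, session)
      b <- crit_eval(node$args[[2]], db, session)
      sub_shared(add_shared(a, b), mul_shared(a, b, session))
    },
    not = complement(crit_eval(node$args[[1]], db, session)),
    stop("invalid criterion node")
  )
}

#' Evaluate a criterion on a plaintext phenotype table
#'
#' Reference counterpart of [evaluate_criterion()] used by the plaintext
#' pipeline and for verification.
#'
#' @param t Phenotype data frame.
#' @param criterion A criterion object or string.
#' @return Integer 0/1 vector of membership.
#' @export
evaluate_criterion_plaintext <- function(t, criterion) {
  if (is.character(criterion)) criterion <- parse_criterion(criterion)
  ev <- function(node) {
    switch(node$op,
      leaf = as.integer(t[[node$attr]] != 0),
      cmp = {
        a <- t[[node$attr]]
        as.integer(switch(node$cmp,
          ">=" = a >= node$const, "<=" = a <= node$const,
          "<" = a < node$const, ">" = a > node$const,
          "==" = a == node$const))
      },
      and = ev(node$args[[1]]) * ev(node$args[[2]]),
      or = 1L - (1L - ev(node$args[[1]])) * (1L - ev(node$args[[2]])),
      not = 1L - ev(node$args[[1]])
    )
  }
  ev(criterion$tree)
}
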
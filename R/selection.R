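# Atom selection mini-language.
#
# Grammar (case-insensitive keywords):
#   expr    := or
#   or      := and ("or" and)*
#   and     := unary ("and" unary)*
#   unary   := "not" unary | "(" expr ")" | term
#   term    := "all" | "none" | "heavy" | "hydrogen" | "backbone"
#            | "protein" | "nucleic"
#            | "name" LIST | "chain" LIST | "resname" LIST | "element" LIST
#            | "resid" RANGELIST
#   LIST      := comma-separated tokens (no spaces inside an item)
#   RANGELIST := comma-separated integers or a:b ranges
#
# e.g. "heavy and chain A", "backbone or name P", "resid 320:336 and name CA"

AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
         "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL","HSD","HSE",
         "HSP","HID","HIE","HIP","MSE","ACE","NME","NMA")
NUC3 <- c("DA","DT","DG","DC","DU","A","T","G","C","U","RA","RU","RG","RC",
          "ADE","THY","GUA","CYT","URA")
BB_PROTEIN <- c("N", "CA", "C", "O", "OXT")
BB_NUCLEIC <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "C5'", "C4'", "C3'",
                "O3'", "O4'", "C1'", "C2'")

#' Select atoms from a topology
#'
#' Resolves a selection to a logical mask over atoms.  `selection` may be a
#' logical vector (length = atom count), an integer vector of atom indices,
#' or a character expression in a small selection language supporting
#' `all`, `none`, `heavy`, `hydrogen`, `backbone`, `protein`, `nucleic`,
#' `name`/`chain`/`resname`/`element`/`resid` terms, combined with
#' `and`, `or`, `not` and parentheses.  `resid` accepts `a:b` ranges.
#'
#' @param top a `"topology"`.
#' @param selection selection expression, logical mask, or atom indices.
#' @return Logical vector over atoms.
#' @examples
#' \dontrun{select_atoms(top, "heavy and chain A")}
#' @export
select_atoms <- function(top, selection) {
  n <- n_atoms(top)
  if (is.logical(selection)) {
    if (length(selection) != n) {
      mdccr_stop("logical selection length must equal atom count",
                 "mdccr_selection_error")
    }
    return(selection)
  }
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > n)) {
      mdccr_stop("atom index selection out of range", "mdccr_selection_error")
    }
    out <- rep(FALSE, n)
    out[idx] <- TRUE
    return(out)
  }
  if (!is.character(selection) || length(selection) != 1L) {
    mdccr_stop("selection must be a string, logical mask or index vector",
               "mdccr_selection_error")
  }
  parse_selection(selection, top)
}

sel_tokenize <- function(s) {
  s <- gsub("\\(", " ( ", s)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

parse_selection <- function(expr, top) {
  toks <- sel_tokenize(expr)
  if (length(toks) == 0L) {
    mdccr_stop("empty selection expression", "mdccr_selection_error")
  }
  env <- new.env()
  env$toks <- toks
  env$pos <- 1L
  peek <- function() if (env$pos <= length(env$toks)) env$toks[env$pos] else NA_character_
  take <- function() { t <- peek(); env$pos <- env$pos + 1L; t }
  a <- top$atoms

  term <- function() {
    t <- take()
    if (is.na(t)) mdccr_stop("unexpected end of selection", "mdccr_selection_error")
    kw <- tolower(t)
    if (kw == "(") {
      v <- p_or()
      if (!identical(tolower(peek()), ")")) {
        mdccr_stop("missing ')' in selection", "mdccr_selection_error")
      }
      take()
      return(v)
    }
    if (kw == "not") return(!term())
    switch(kw,
      all = rep(TRUE, nrow(a)),
      none = rep(FALSE, nrow(a)),
      heavy = a$element != "H",
      hydrogen = a$element == "H",
      protein = a$resname %in% AA3,
      nucleic = a$resname %in% NUC3,
      backbone = (a$resname %in% AA3 & a$name %in% BB_PROTEIN) |
                 (a$resname %in% NUC3 & a$name %in% BB_NUCLEIC) |
                 (!a$resname %in% c(AA3, NUC3) & a$name %in% c(BB_PROTEIN, "P")),
      name = ,
      chain = ,
      resname = ,
      element = {
        arg <- take()
        if (is.na(arg)) {
          mdccr_stop(paste0("'", kw, "' needs an argument"), "mdccr_selection_error")
        }
        vals <- strsplit(arg, ",")[[1]]
        fld <- switch(kw, name = a$name, chain = a$chain,
                      resname = a$resname, element = a$element)
        if (kw == "element") vals <- toupper(vals)
        fld %in% vals
      },
      resid = {
        arg <- take()
        if (is.na(arg)) mdccr_stop("'resid' needs an argument", "mdccr_selection_error")
        hit <- rep(FALSE, nrow(a))
        for (piece in strsplit(arg, ",")[[1]]) {
          if (grepl(":", piece, fixed = TRUE)) {
            ab <- as.integer(strsplit(piece, ":", fixed = TRUE)[[1]])
            hit <- hit | (a$resno >= ab[1] & a$resno <= ab[2])
          } else {
            hit <- hit | a$resno == as.integer(piece)
          }
        }
        hit
      },
      mdccr_stop(paste0("unknown selection term: '", t, "'"),
                 "mdccr_selection_error")
    )
  }
  p_and <- function() {
    v <- term()
    while (identical(tolower(peek()), "and")) { take(); v <- v & term() }
    v
  }
  p_or <- function() {
    v <- p_and()
    while (identical(tolower(peek()), "or")) { take(); v <- v | p_and() }
    v
  }
  out <- p_or()
  if (env$pos <= length(env$toks)) {
    mdccr_stop(paste0("trailing tokens in selection near '", peek(), "'"),
               "mdccr_selection_error")
  }
  out
}
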
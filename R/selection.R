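#' Atom selections
#'
#' Resolve a selection expression against a model. The expression is a
#' comma- or `and`-separated list of clauses:
#'
#' * `chain A H` — chain identifiers
#' * `residues 712-766` (also `resno 712:766`, mixed lists `769-771 784`)
#' * `atoms N,CA,C` (also `name CA`)
#' * `calpha` — shorthand for `atoms CA`
#' * `backbone` — shorthand for `atoms N,CA,C,O`
#' * `heavy` — drop hydrogens (element not H)
#'
#' Clauses combine with AND. The result is an ordered set of atom indices
#' into the model, stable with model atom order; running the same expression
#' twice yields identical indices. An empty result is returned (with a
#' warning) rather than an error, so callers can decide.
#'
#' @param model a [mol_model()].
#' @param expression selection expression string (see Details).
#' @return An integer vector of class `atom_sel` with a `provenance`
#'   attribute recording the expression.
#' @examples
#' \dontrun{
#' sel <- select_atoms(model, "residues 712-766, atoms CA")
#' }
#' @export
select_atoms <- function(model, expression) {
  if (!inherits(model, "mol_model")) stop("model must be a mol_model")
  if (!is.character(expression) || length(expression) != 1L || !nzchar(trimws(expression)))
    stop("selection parse error: expression must be a non-empty string")
  expr <- gsub("–|—", "-", expression)  # normalize dashes

  kw <- c("chain", "chains", "residue", "residues", "resno", "resid",
          "atom", "atoms", "name", "names", "heavy", "backbone", "calpha")
  # split into clauses at commas/`and` that are followed by a keyword
  parts <- strsplit(expr, sprintf("(,|\\band\\b)\\s*(?=\\b(%s)\\b)",
                                  paste(kw, collapse = "|")),
                    perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("selection parse error: '", expression, "'")

  keep <- rep(TRUE, n_atoms(model))
  at <- model$atoms
  for (p in parts) {
    toks <- strsplit(trimws(p), "[,[:space:]]+")[[1]]
    key <- tolower(toks[1])
    vals <- toks[-1]
    if (!key %in% kw) stop("selection parse error: unknown clause '", p, "'")
    if (key %in% c("heavy", "backbone", "calpha")) {
      if (length(vals)) stop("selection parse error: '", key, "' takes no values")
      keep <- keep & switch(key,
        heavy    = toupper(at$elesy) != "H",
        backbone = at$elety %in% c("N", "CA", "C", "O"),
        calpha   = at$elety == "CA")
    } else {
      if (!length(vals)) stop("selection parse error: '", key, "' needs values")
      if (key %in% c("chain", "chains")) {
        keep <- keep & at$chain %in% vals
      } else if (key %in% c("residue", "residues", "resno", "resid")) {
        keep <- keep & at$resno %in% parse_ranges(vals)
      } else {
        keep <- keep & at$elety %in% toupper(vals)
      }
    }
  }
  idx <- which(keep)
  if (!length(idx)) warning("selection '", expression, "' matched no atoms")
  new_atom_sel(idx, expression)
}

parse_ranges <- function(vals) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+[-:][0-9]+$", v)) {
      sep <- if (grepl(":", v)) ":" else "-"
      ab <- as.integer(strsplit(v, sep, fixed = TRUE)[[1]][1:2])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      stop("selection parse error: bad residue token '", v, "'")
    }
  }
  out
}

new_atom_sel <- function(idx, provenance = "") {
  structure(as.integer(idx), class = "atom_sel", provenance = provenance)
}

#' @export
print.atom_sel <- function(x, ...) {
  cat(sprintf("<atom_sel> %d atoms  [%s]\n", length(x), attr(x, "provenance")))
  invisible(x)
}

# subsetting keeps the class
#' @export
`[.atom_sel` <- function(x, i) {
  new_atom_sel(unclass(x)[i], attr(x, "provenance"))
}

#' Combine selections (set union, model order preserved)
#' @param ... `atom_sel` objects over the same model.
#' @export
union_sel <- function(...) {
  sels <- list(...)
  idx <- sort(unique(unlist(lapply(sels, as.integer))))
  new_atom_sel(idx, paste(vapply(sels, function(s) attr(s, "provenance"), ""),
                          collapse = " | "))
}

validate_sel <- function(sel, model) {
  idx <- as.integer(sel)
  if (anyDuplicated(idx)) stop("selection indices must be unique")
  if (length(idx) && (min(idx) < 1L || max(idx) > n_atoms(model)))
    stop("selection indices out of range for this model")
  invisible(idx)
}
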
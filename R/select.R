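# Atom selection mini-language.
#
# Grammar (keywords lower-case, values terminated by the next keyword,
# operator or parenthesis):
#   expr     := and_expr ('or' and_expr)*
#   and_expr := not_expr ('and' not_expr)*
#   not_expr := 'not' not_expr | '(' expr ')' | predicate | named
#   predicate:= 'resname' VALUE+ | 'name' GLOB+ | 'element' SYMBOL+
#             | 'resid' (INT | INT 'to' INT | INT:INT)+
#   named    := 'water_oxygen' | 'lipid_carbon'

.water_resnames <- c("SOL", "HOH", "WAT", "TIP3", "TIP3P")

#' Select atoms by textual query
#'
#' Resolves a selection expression against a system and returns a
#' deterministic, order-preserving [atom_set].  Two named selections cover
#' the two species the occupancy analysis counts: `water_oxygen` (oxygen
#' atoms of common water residue names) and `lipid_carbon` (carbon atoms of
#' lipid residues, the residue names given by `lipid_resnames`).
#'
#' @param system a [molecular_system].
#' @param spec selection string, e.g. `"resname POPC and element C"`,
#'   `"name OW*"`, `"resid 10 to 20 or resname THR"`, `"water_oxygen"`.
#' @param lipid_resnames residue names treated as lipids by the
#'   `lipid_carbon` named selection (default `"POPC"`).
#' @return An [atom_set]; empty selections are valid and return an empty set.
#' @examples
#' s <- molecular_system(data.frame(
#'   atom_name = c("OW", "HW1", "HW2"), residue_name = "SOL", residue_id = 1L))
#' length(select_atoms(s, "water_oxygen")$indices)
#' @export
select_atoms <- function(system, spec, lipid_resnames = "POPC") {
  stopifnot(inherits(system, "molecular_system"))
  if (!is.character(spec) || length(spec) != 1L || !nzchar(trimws(spec)))
    stop("select_atoms: spec must be a nonempty string", call. = FALSE)
  tokens <- tokenize_selection(spec)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens; st$pos <- 1L
  st$atoms <- system$atoms; st$lipid_resnames <- lipid_resnames
  mask <- parse_or(st)
  if (st$pos <= length(st$tokens))
    sel_error(st, paste0("unexpected token '", st$tokens[st$pos], "'"))
  atom_set(which(mask) - 1L, selection_spec = spec, n_atoms = system$n_atoms)
}

tokenize_selection <- function(spec) {
  spec <- gsub("([()])", " \\1 ", spec)
  tokens <- strsplit(trimws(spec), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

sel_error <- function(st, msg) {
  stop("selection parse error at token ", st$pos, ": ", msg, call. = FALSE)
}

peek <- function(st) if (st$pos <= length(st$tokens)) st$tokens[st$pos] else NA_character_
advance <- function(st) { tok <- peek(st); st$pos <- st$pos + 1L; tok }

.sel_keywords <- c("and", "or", "not", "(", ")",
                   "resname", "name", "element", "resid")

parse_or <- function(st) {
  mask <- parse_and(st)
  while (!is.na(peek(st)) && peek(st) == "or") {
    advance(st)
    mask <- mask | parse_and(st)
  }
  mask
}

parse_and <- function(st) {
  mask <- parse_not(st)
  while (!is.na(peek(st)) && peek(st) == "and") {
    advance(st)
    mask <- mask & parse_not(st)
  }
  mask
}

parse_not <- function(st) {
  tok <- peek(st)
  if (is.na(tok)) sel_error(st, "unexpected end of expression")
  if (tok == "not") {
    advance(st)
    return(!parse_not(st))
  }
  if (tok == "(") {
    advance(st)
    mask <- parse_or(st)
    if (is.na(peek(st)) || peek(st) != ")") sel_error(st, "expected ')'")
    advance(st)
    return(mask)
  }
  parse_predicate(st)
}

collect_values <- function(st, what) {
  vals <- character(0)
  while (!is.na(peek(st)) && !(peek(st) %in% .sel_keywords)) {
    vals <- c(vals, advance(st))
  }
  if (!length(vals)) sel_error(st, paste0("expected at least one ", what))
  vals
}

parse_predicate <- function(st) {
  a <- st$atoms
  tok <- advance(st)
  switch(tok,
    water_oxygen = a$residue_name %in% .water_resnames &
                     startsWith(a$atom_name, "O"),
    lipid_carbon = a$residue_name %in% st$lipid_resnames & a$element == "C",
    resname = a$residue_name %in% collect_values(st, "residue name"),
    element = a$element %in% collect_values(st, "element symbol"),
    name = {
      globs <- collect_values(st, "atom name pattern")
      Reduce(`|`, lapply(globs, function(g)
        grepl(utils::glob2rx(g), a$atom_name)))
    },
    resid = parse_resid(st, a),
    {
      st$pos <- st$pos - 1L  # report the offending token's own position
      sel_error(st, paste0("unknown predicate or selection '", tok, "'"))
    })
}

parse_resid <- function(st, a) {
  vals <- collect_values(st, "residue id")
  mask <- rep(FALSE, nrow(a))
  i <- 1L
  while (i <= length(vals)) {
    v <- vals[i]
    if (grepl("^-?[0-9]+:[-0-9]+$", v)) {
      lohi <- as.integer(strsplit(v, ":")[[1]])
      mask <- mask | (a$residue_id >= lohi[1] & a$residue_id <= lohi[2])
      i <- i + 1L
    } else if (i + 2L <= length(vals) && vals[i + 1L] == "to") {
      lo <- suppressWarnings(as.integer(v))
      hi <- suppressWarnings(as.integer(vals[i + 2L]))
      if (is.na(lo) || is.na(hi)) sel_error(st, "bad resid range")
      mask <- mask | (a$residue_id >= lo & a$residue_id <= hi)
      i <- i + 3L
    } else {
      ri <- suppressWarnings(as.integer(v))
      if (is.na(ri)) sel_error(st, paste0("bad residue id '", v, "'"))
      mask <- mask | a$residue_id == ri
      i <- i + 1L
    }
  }
  mask
}
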
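# PDB structure handling: fixed-column read/write, atom selection,
# mass-weighted centers of mass and the principal pulling axis.

# Standard atomic masses (amu). Unknown elements fall back to 12.011 with a
# warning so coarse-grained/toy inputs without element columns still work.
.ELEMENT_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, MG = 24.305, K = 39.098, CA = 40.078, FE = 55.845,
  ZN = 65.38, MN = 54.938, CU = 63.546, SE = 78.971, X = 12.011
)
names(.ELEMENT_MASS)[names(.ELEMENT_MASS) == "NA."] <- "NA"

#' Mass of a chemical element
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu; unknown symbols yield 12.011
#'   with a warning.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .ELEMENT_MASS[key]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning("unknown element symbol(s) ", paste(unique(key[unknown]), collapse = ", "),
            "; using fallback mass 12.011 amu", call. = FALSE)
    m[unknown] <- 12.011
  }
  unname(m)
}

# Infer element from the 4-character atom-name field when columns 77-78 are
# blank. A two-letter element (FE, MG, ...) is left-justified into column 13;
# protein atoms start in column 14, so a blank column 13 means one letter.
infer_element <- function(name_raw) {
  vapply(name_raw, function(nm) {
    nm4 <- formatC(nm, width = 4, flag = "-")
    stripped <- gsub("[0-9' ]", "", toupper(nm4))
    if (nchar(stripped) == 0L) return("X")
    # 4-character hydrogen names (e.g. HG11) spill into column 13; catch them
    # before the two-letter-element rule would read HG as mercury.
    if (substr(stripped, 1, 1) == "H" && grepl("[0-9]", nm4)) return("H")
    two <- substr(stripped, 1, 2)
    if (substr(nm4, 1, 1) != " " && two %in% names(.ELEMENT_MASS)) return(two)
    substr(stripped, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

parse_pdb_atom_lines <- function(lines, line_numbers) {
  sub_col <- function(a, b) substr(lines, a, b)
  num_field <- function(a, b, what) {
    txt <- trimws(sub_col(a, b))
    val <- suppressWarnings(as.numeric(txt))
    bad <- is.na(val) & txt != ""
    if (any(bad)) {
      pf_stop_format(sprintf("malformed %s field on line %d: '%s'",
                             what, line_numbers[which(bad)[1]], txt[which(bad)[1]]))
    }
    val
  }
  x <- num_field(31, 38, "x-coordinate")
  y <- num_field(39, 46, "y-coordinate")
  z <- num_field(47, 54, "z-coordinate")
  if (any(is.na(x) | is.na(y) | is.na(z))) {
    i <- which(is.na(x) | is.na(y) | is.na(z))[1]
    pf_stop_format(sprintf("missing coordinate on line %d", line_numbers[i]))
  }
  occ <- num_field(55, 60, "occupancy"); occ[is.na(occ)] <- 1
  beta <- num_field(61, 66, "B-factor"); beta[is.na(beta)] <- 0
  serial <- suppressWarnings(as.integer(trimws(sub_col(7, 11))))
  serial[is.na(serial)] <- seq_along(lines)[is.na(serial)]
  name_raw <- sub_col(13, 16)
  elem <- trimws(sub_col(77, 78))
  need <- elem == ""
  if (any(need)) elem[need] <- infer_element(name_raw[need])
  resseq <- suppressWarnings(as.integer(trimws(sub_col(23, 26))))
  resseq[is.na(resseq)] <- 0L
  data.frame(
    record = trimws(sub_col(1, 6)),
    serial = serial,
    name = trimws(name_raw),
    name_raw = name_raw,
    resname = trimws(sub_col(18, 20)),
    chain = sub_col(22, 22),
    resseq = resseq,
    x = x, y = y, z = z,
    occupancy = occ, beta = beta,
    segid = trimws(sub_col(73, 76)),
    element = toupper(elem),
    stringsAsFactors = FALSE
  )
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records by their fixed columns (wwPDB v3.3). The
#' element is taken from columns 77-78 when present, otherwise inferred from
#' the atom-name field; per-atom masses are assigned from the element. For
#' multi-model files only the first MODEL defines the structure (use
#' [read_trajectory()] for all frames).
#'
#' @param path path to a PDB file.
#' @return an object of class `pdb_structure`: a list with `atoms` (a
#'   data frame, one row per atom, in file order) and `title`.
#' @seealso [write_pdb()], [atom_select()], [center_of_mass()]
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) pf_stop_input(sprintf("PDB file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  title <- paste(trimws(substring(lines[startsWith(lines, "TITLE")], 11)), collapse = " ")
  # restrict to the first model when MODEL records are present
  first_end <- which(startsWith(lines, "ENDMDL"))
  scope <- if (length(first_end)) seq_len(first_end[1]) else seq_along(lines)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  keep <- which(is_atom & seq_along(lines) %in% scope)
  if (length(keep) == 0L) pf_stop_format(sprintf("no ATOM/HETATM records in %s", path))
  atoms <- parse_pdb_atom_lines(lines[keep], keep)
  atoms$mass <- suppressWarnings(element_mass(atoms$element))
  structure(list(atoms = atoms, title = title), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("pdb_structure: %d atoms, %d chain(s)%s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

new_structure <- function(atoms, title = "") {
  if (is.null(atoms$name_raw)) {
    atoms$name_raw <- vapply(seq_len(nrow(atoms)), function(i) {
      nm <- atoms$name[i]
      if (nchar(nm) >= 4L || nchar(atoms$element[i]) > 1L)
        formatC(nm, width = 4, flag = "-")
      else
        formatC(paste0(" ", nm), width = 4, flag = "-")
    }, character(1))
  }
  if (is.null(atoms$record)) atoms$record <- "ATOM"
  if (is.null(atoms$segid)) atoms$segid <- ""
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  structure(list(atoms = atoms, title = title), class = "pdb_structure")
}

format_pdb_atom_lines <- function(atoms) {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
          atoms$record, atoms$serial %% 100000L, atoms$name_raw, atoms$resname,
          atoms$chain, atoms$resseq, atoms$x, atoms$y, atoms$z,
          atoms$occupancy, atoms$beta, atoms$segid,
          formatC(atoms$element, width = 2))
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records; coordinates with 3 decimals,
#' occupancy and B-factor with 2. Optional per-atom overrides replace the
#' occupancy/B-factor columns (used to tag fixed and SMD atoms for NAMD).
#'
#' @param structure a `pdb_structure`.
#' @param path output file path.
#' @param beta_override,occupancy_override optional named numeric vectors or
#'   plain numeric vectors indexed by atom position (1-based) giving
#'   replacement values; e.g. `beta_override = c("3" = 1)` sets atom 3.
#' @return invisibly, the path.
#' @export
write_pdb <- function(structure, path, beta_override = NULL, occupancy_override = NULL) {
  stopifnot(inherits(structure, "pdb_structure"))
  atoms <- structure$atoms
  if (nrow(atoms) == 0L) pf_stop_input("refusing to write an empty structure")
  apply_override <- function(column, ov) {
    if (is.null(ov)) return(column)
    idx <- if (!is.null(names(ov))) as.integer(names(ov)) else seq_along(ov)
    if (any(idx < 1L | idx > length(column))) pf_stop_input("override index out of range")
    column[idx] <- as.numeric(ov)
    column
  }
  atoms$beta <- apply_override(atoms$beta, beta_override)
  atoms$occupancy <- apply_override(atoms$occupancy, occupancy_override)
  lines <- c(
    if (nzchar(structure$title)) sprintf("TITLE     %s", structure$title),
    format_pdb_atom_lines(atoms),
    "END"
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) pf_stop_input(sprintf("cannot write PDB file: %s", path))
  invisible(path)
}

## ---- atom selection -------------------------------------------------------

# Minimal deterministic selection grammar:
#   chain <ID>  |  resid <a>[-<b>]  |  name <N>  |  segid <S>
# combinable with and / or / not and parentheses; keywords case-insensitive.
tokenize_selection <- function(expression) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, expression)[[1]]
  if (m[1] == -1L) pf_stop_format("empty selection expression")
  toks <- regmatches(expression, gregexpr(pat, expression))[[1]]
  data.frame(token = toks, pos = as.integer(m), stringsAsFactors = FALSE)
}

eval_selection <- function(toks, atoms) {
  i <- 0L
  n <- nrow(toks)
  peek <- function() if (i < n) toks$token[i + 1L] else NA_character_
  advance <- function() { i <<- i + 1L; toks$token[i] }
  err <- function(msg) {
    at <- if (i < n) sprintf(" at position %d ('%s')", toks$pos[i + 1L], toks$token[i + 1L]) else " at end of expression"
    pf_stop_format(paste0("selection syntax error: ", msg, at))
  }
  parse_primary <- function() {
    kw <- tolower(peek())
    if (is.na(kw)) err("expected a selection term")
    if (kw == "(") {
      advance()
      v <- parse_or()
      if (!identical(peek(), ")")) err("expected ')'")
      advance()
      return(v)
    }
    if (kw == "not") { advance(); return(!parse_primary()) }
    if (!kw %in% c("chain", "resid", "name", "segid")) err("unknown keyword")
    advance()
    val <- peek()
    if (is.na(val) || val %in% c("(", ")")) err(sprintf("'%s' needs a value", kw))
    advance()
    switch(kw,
      chain = atoms$chain == val,
      segid = atoms$segid == val,
      name = toupper(atoms$name) == toupper(val),
      resid = {
        if (grepl("^-?[0-9]+--?[0-9]+$", val)) {
          parts <- regmatches(val, regexec("^(-?[0-9]+)-(-?[0-9]+)$", val))[[1]]
          a <- as.integer(parts[2]); b <- as.integer(parts[3])
          atoms$resseq >= min(a, b) & atoms$resseq <= max(a, b)
        } else if (grepl("^-?[0-9]+$", val)) {
          atoms$resseq == as.integer(val)
        } else err("resid expects <n> or <a>-<b>")
      })
  }
  parse_and <- function() {
    v <- parse_primary()
    while (!is.na(peek()) && tolower(peek()) == "and") { advance(); v <- v & parse_primary() }
    v
  }
  parse_or <- function() {
    v <- parse_and()
    while (!is.na(peek()) && tolower(peek()) == "or") { advance(); v <- v | parse_and() }
    v
  }
  v <- parse_or()
  if (i != n) err("trailing tokens")
  v
}

#' Resolve an atom selection
#'
#' Selection grammar: `chain <ID>`, `resid <a>-<b>` (or a single residue
#' number), `name <N>`, `segid <S>`, combinable with `and`, `or`, `not` and
#' parentheses. Keywords are case-insensitive; atom names match
#' case-insensitively. Resolution is deterministic: indices come back in
#' structure order.
#'
#' @param structure a `pdb_structure`.
#' @param expression selection string, or an integer vector of 1-based atom
#'   indices (passed through after range checking).
#' @return sorted integer vector of 1-based atom indices. An empty result is
#'   allowed but raises a warning.
#' @examples
#' \dontrun{atom_select(s, "chain A and resid 1-30")}
#' @export
atom_select <- function(structure, expression) {
  stopifnot(inherits(structure, "pdb_structure"))
  if (is.numeric(expression)) {
    idx <- as.integer(expression)
    if (any(idx < 1L | idx > nrow(structure$atoms))) pf_stop_input("atom index out of range")
    return(sort(unique(idx)))
  }
  mask <- eval_selection(tokenize_selection(expression), structure$atoms)
  idx <- which(mask)
  if (length(idx) == 0L) warning(sprintf("selection '%s' matched no atoms", expression), call. = FALSE)
  idx
}

## ---- centers of mass and the pulling axis ---------------------------------

#' Center of mass of an atom selection
#'
#' @param structure a `pdb_structure`.
#' @param indices integer atom indices (1-based) or a selection string;
#'   `NULL` means all atoms.
#' @param weighting `"mass"` (default) for the mass-weighted center,
#'   `"geometric"` for the unweighted centroid.
#' @return numeric length-3 vector in Angstrom.
#' @export
center_of_mass <- function(structure, indices = NULL, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  a <- structure$atoms
  if (is.null(indices)) indices <- seq_len(nrow(a))
  if (is.character(indices)) indices <- atom_select(structure, indices)
  if (length(indices) == 0L) pf_stop_input("empty selection: center of mass undefined")
  w <- if (weighting == "mass") a$mass[indices] else rep(1, length(indices))
  c(sum(w * a$x[indices]), sum(w * a$y[indices]), sum(w * a$z[indices])) / sum(w)
}

#' Principal pulling axis of a two-body complex
#'
#' The unit vector from the fixed group's center of mass toward the pulled
#' group's center of mass. All pulling directions are parameterised by their
#' polar angle theta from this axis.
#'
#' @inheritParams center_of_mass
#' @param fixed,pulled selection strings or index vectors for the two groups.
#' @return unit numeric length-3 vector.
#' @export
principal_axis <- function(structure, fixed, pulled, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  v <- center_of_mass(structure, pulled, weighting) - center_of_mass(structure, fixed, weighting)
  len <- sqrt(sum(v^2))
  if (len < 1e-6) pf_stop_input("degenerate axis: the two centers of mass coincide (< 1e-6 A apart)")
  v / len
}
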
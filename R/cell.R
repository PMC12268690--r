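# Minimal crystallographic cell arithmetic and a cell-block CIF reader.
# Only the cell/formula subset of CIF is parsed; loops, symmetry operators
# and reflection data are out of scope.

#' Unit-cell parameters
#'
#' @param a,b,c cell lengths, angstrom
#' @param alpha,beta,gamma cell angles, degrees
#' @param space_group space-group symbol (free text)
#' @param Z formula units per cell
#' @param formula chemical formula, element-count notation (e.g. "C7H8N4O2")
#' @param formula_weight g/mol; computed from `formula` when omitted
#' @return object of class `cell_params`
#' @examples
#' theophylline <- cell_params(24.2655, 3.76210, 8.4743,
#'                             Z = 4, formula = "C7H8N4O2")
#' cell_volume(theophylline)
#' @export
cell_params <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                        space_group = NA_character_, Z = NA_integer_,
                        formula = NA_character_, formula_weight = NULL) {
  .check_positive(c(a, b, c), "cell lengths")
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie in (0, 180) degrees", call. = FALSE)
  }
  fw <- if (!is.null(formula_weight)) {
    .check_positive(formula_weight, "formula_weight")
    formula_weight
  } else if (!is.na(formula)) {
    molecular_weight(formula)
  } else {
    NA_real_
  }
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 space_group = space_group, Z = Z,
                 formula = formula, formula_weight = fw),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.4f b=%.4f c=%.4f A, alpha=%.2f beta=%.2f gamma=%.2f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  if (!is.na(x$space_group)) cat("  space group:", x$space_group, "\n")
  if (!is.na(x$Z)) cat("  Z =", x$Z, "\n")
  if (!is.na(x$formula)) {
    cat(sprintf("  formula %s, Fw = %.2f g/mol\n", x$formula, x$formula_weight))
  }
  cat(sprintf("  V = %.2f A^3\n", cell_volume(x)))
  invisible(x)
}

# strip CIF standard uncertainty: "24.2655(8)" -> 24.2655
.cif_numeric <- function(value, tag) {
  v <- sub("\\(\\d+\\)$", "", value)
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) {
    stop(sprintf("malformed numeric value '%s' for CIF tag %s", value, tag),
         call. = FALSE)
  }
  out
}

#' Read unit-cell parameters from a CIF cell block
#'
#' Parses the `_cell_length_*`, `_cell_angle_*`, `_cell_formula_units_Z`,
#' `_symmetry_space_group_name_H-M` (or `_space_group_name_H-M_alt`) and
#' `_chemical_formula_sum`/`_chemical_formula_moiety` tags of a single data
#' block. Standard-uncertainty parentheses are stripped. Loops, symmetry
#' operators and atom sites are ignored.
#'
#' @param path path to a CIF file
#' @return a [cell_params()] object
#' @examples
#' cif <- system.file("extdata", "theophylline_form_ii_cell.cif",
#'                    package = "stepkin")
#' read_cif_cell(cif)
#' @export
read_cif_cell <- function(path) {
  if (!file.exists(path)) stop("CIF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty CIF file: ", path, call. = FALSE)

  get_tag <- function(tag, required = TRUE) {
    hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (length(hit) == 0) {
      if (required) {
        stop(sprintf("CIF parse error: mandatory tag %s missing", tag),
             call. = FALSE)
      }
      return(NA_character_)
    }
    val <- trimws(sub(paste0("^", tag, "\\s*"), "", hit[1]))
    gsub("^'|'$", "", val)
  }

  a <- .cif_numeric(get_tag("_cell_length_a"), "_cell_length_a")
  b <- .cif_numeric(get_tag("_cell_length_b"), "_cell_length_b")
  cc <- .cif_numeric(get_tag("_cell_length_c"), "_cell_length_c")
  al <- .cif_numeric(get_tag("_cell_angle_alpha"), "_cell_angle_alpha")
  be <- .cif_numeric(get_tag("_cell_angle_beta"), "_cell_angle_beta")
  ga <- .cif_numeric(get_tag("_cell_angle_gamma"), "_cell_angle_gamma")
  Zs <- get_tag("_cell_formula_units_Z", required = FALSE)
  Z <- if (is.na(Zs)) NA_integer_ else as.integer(.cif_numeric(Zs, "_cell_formula_units_Z"))
  sg <- get_tag("_symmetry_space_group_name_H-M", required = FALSE)
  if (is.na(sg)) sg <- get_tag("_space_group_name_H-M_alt", required = FALSE)
  form <- get_tag("_chemical_formula_sum", required = FALSE)
  if (is.na(form)) form <- get_tag("_chemical_formula_moiety", required = FALSE)
  if (!is.na(form)) form <- gsub("[' ]", "", form)

  cell_params(a, b, cc, al, be, ga, space_group = sg, Z = Z, formula = form)
}

# "C7H8N4O2" -> named counts c(C = 7, H = 8, N = 4, O = 2)
.parse_formula <- function(formula) {
  formula <- gsub("\\s", "", formula)
  m <- gregexpr("[A-Z][a-z]?\\d*", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?\\d*", formula))[[1]]
  if (length(tokens) == 0 || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse chemical formula: ", formula, call. = FALSE)
  }
  elems <- sub("\\d+$", "", tokens)
  counts <- as.numeric(ifelse(grepl("\\d+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  tapply(counts, elems, sum)
}

#' Molecular weight of a chemical formula
#'
#' Sums standard atomic weights (IUPAC 2021, 5 significant figures) over the
#' element counts of the formula.
#'
#' @param formula element-count formula, e.g. `"C7H8N4O2"`
#' @return molar mass, g/mol
#' @examples
#' molecular_weight("C7H8N4O2")  # theophylline, 180.17
#' @export
molecular_weight <- function(formula) {
  counts <- .parse_formula(formula)
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(counts * .atomic_weights[names(counts)])
}

#' Unit-cell volume
#'
#' General triclinic volume
#' \deqn{V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma
#'   + 2\cos\alpha\cos\beta\cos\gamma},}
#' which reduces to \eqn{abc} for orthorhombic cells.
#'
#' @param cell a [cell_params()] object
#' @return volume, cubic angstrom
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "cell_params"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("degenerate cell: zero or imaginary volume", call. = FALSE)
  cell$a * cell$b * cell$c * sqrt(disc)
}

#' Calculated crystal density
#'
#' \eqn{D_c = Z \cdot F_w / (N_A V)} with the cell volume converted to
#' cm^3.
#'
#' @param cell a [cell_params()] object with `Z` and a formula (or
#'   `formula_weight`) set
#' @return density, g/cm^3
#' @examples
#' calc_density(cell_params(24.2655, 3.76210, 8.4743, Z = 4,
#'                          formula = "C7H8N4O2"))
#' @export
calc_density <- function(cell) {
  stopifnot(inherits(cell, "cell_params"))
  if (is.na(cell$Z)) stop("`Z` missing from cell", call. = FALSE)
  if (is.na(cell$formula_weight)) {
    stop("formula (or formula_weight) missing from cell", call. = FALSE)
  }
  V_cm3 <- cell_volume(cell) * 1e-24
  cell$Z * cell$formula_weight / (sk_constants$N_A * V_cm3)
}

#' Admissible AFM step heights on the (200) face
#'
#' Layers on (200) advance along the a axis; full steps are one unit-cell
#' parameter high and sub-steps are half a cell (the two halves being
#' glide-related). The default is the room-temperature AFM value
#' |a| = 2.413 nm rather than the 100 K single-crystal cell.
#'
#' @param a_nm unit-cell a parameter, nm
#' @return list with elements `full` and `half` (nm)
#' @examples
#' step_heights()  # full 2.413, half 1.2065 nm
#' @export
step_heights <- function(a_nm = 2.413) {
  .check_positive(a_nm, "a_nm")
  list(full = a_nm, half = a_nm / 2)
}
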
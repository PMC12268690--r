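# Shared fixtures and independent oracles used across test files.

# Write a minimal CIF cell block (the published theophylline Form II cell)
# to a temp file and return its path.
write_theophylline_cif <- function(path = tempfile(fileext = ".cif")) {
  writeLines(c(
    "data_theophylline_form_II",
    "_symmetry_space_group_name_H-M   'P n a 21'",
    "_cell_length_a                   24.2655(8)",
    "_cell_length_b                   3.76210(10)",
    "_cell_length_c                   8.4743(2)",
    "_cell_angle_alpha                90",
    "_cell_angle_beta                 90",
    "_cell_angle_gamma                90",
    "_cell_formula_units_Z            4",
    "_chemical_formula_sum            'C7 H8 N4 O2'"
  ), path)
  path
}

# Independent oracle: unit-cell volume as sqrt(det(G)) of the metric tensor.
cell_volume_metric_oracle <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  G <- matrix(c(a * a, a * b * cg, a * c * cb,
                a * b * cg, b * b, b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  sqrt(det(G))
}

# Independent oracle: kink density of the restricted three-state bond model
# by explicit Boltzmann enumeration over height differences {-1, 0, +1}.
kink_density_enumeration_oracle <- function(omega_J_mol, T_K) {
  s <- c(-1, 0, 1)
  w <- exp(-omega_J_mol * abs(s) / (8.314462618 * T_K))
  sum(abs(s) * w) / sum(w)
}

# Independent oracle: element-count map by token-by-token parse.
formula_counts_oracle <- function(formula) {
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?|\\d+", formula))[[1]]
  counts <- list()
  i <- 1
  while (i <= length(tokens)) {
    el <- tokens[i]
    n <- 1
    if (i < length(tokens) && grepl("^\\d+$", tokens[i + 1])) {
      n <- as.numeric(tokens[i + 1])
      i <- i + 1
    }
    counts[[el]] <- (counts[[el]] %||% 0) + n
    i <- i + 1
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A three-law fit bundle for a v(C) dataset.
fit_all_laws <- function(vc) {
  list(fit_linear_bcf(vc), fit_power_law(vc), fit_kink_limited(vc))
}
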
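# Fixtures are generated in code; nothing is stored on disk.

# Build a protein_structure directly from typed coordinates.
fixture_structure <- function(xyz, element = "C", residue = "ALA",
                              hetero = FALSE, id = "fix") {
  n <- nrow(xyz)
  element <- rep_len(element, n)
  residue <- rep_len(residue, n)
  hetero <- rep_len(hetero, n)
  if (all(hetero)) {           # need one polymer atom far away
    xyz <- rbind(xyz, c(999, 999, 999))
    element <- c(element, "C"); residue <- c(residue, "GLY")
    hetero <- c(hetero, FALSE)
    n <- n + 1
  }
  atoms <- data.frame(
    serial = seq_len(n), atom_name = ifelse(element == "C", "CA", paste0(element, "1")),
    element = element, residue_name = residue, residue_seq = seq_len(n),
    chain_id = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_hetero = hetero, stringsAsFactors = FALSE)
  pocketsig:::new_structure(id, atoms)
}

# A pocket object straight from typed coordinates.
fixture_pocket <- function(xyz, element = "C", residue = "ALA", id = "fix",
                           rank = 1L, volume = 0) {
  st <- fixture_structure(xyz, element, residue, id = id)
  pocketsig:::new_pocket(st, seq_len(nrow(xyz)), volume = volume, rank = rank)
}

# Pocket carrying a motif template's coordinates and types.
motif_pocket <- function(motif, id = "template") {
  aa3 <- names(pocketsig:::AA3TO1)[match(motif$residue, pocketsig:::AA3TO1)]
  fixture_pocket(as.matrix(motif[, c("x", "y", "z")]),
                 element = motif$element, residue = aa3, id = id)
}

# Random typed pocket for property tests.
random_pocket <- function(n, seed, spread = 6) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n, -spread, spread), ncol = 3)
  elems <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  res <- sample(names(pocketsig:::AA3TO1), n, replace = TRUE)
  fixture_pocket(xyz, elems, res, id = paste0("rp", seed))
}

random_rigid <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              nrow = 3, byrow = TRUE)
  list(R = R, t = runif(3, -15, 15))
}

transform_pocket <- function(pocket, rigid) {
  xyz <- as.matrix(pocket$atoms[, c("x", "y", "z")]) %*% t(rigid$R)
  xyz <- sweep(xyz, 2, -rigid$t)
  fixture_pocket(xyz, pocket$atoms$element, pocket$atoms$residue_name,
                 id = paste0(pocket$structure_id, "_T"))
}

# Hollow spherical shell of atoms (optionally with a mouth of the given
# aperture radius around +z), used for pocket-finder tests.
shell_structure <- function(radius = 12, spacing = 2.2, mouth_radius = 0,
                            centre = c(0, 0, 0), id = "shell",
                            extra_xyz = NULL) {
  K <- max(60L, as.integer(round(4 * pi * radius^2 / (spacing^2 * 0.8))))
  dirs <- pocketsig:::fibonacci_sphere(K)
  if (mouth_radius > 0) {
    # drop atoms whose direction lies within the mouth cone
    cosc <- cos(asin(pmin(1, mouth_radius / radius)))
    dirs <- dirs[dirs[, 3] < cosc, , drop = FALSE]
  }
  xyz <- dirs * radius
  xyz <- sweep(xyz, 2, -centre)
  if (!is.null(extra_xyz)) xyz <- rbind(xyz, extra_xyz)
  fixture_structure(xyz, id = id)
}

# Minimal hand-written PDB content (3 atoms + optional extras).
toy_pdb_lines <- function() {
  c("HEADER    TOY",
    "ATOM      1  N   MET A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  MET A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  O   MET A   1      12.669   7.060  -5.092  1.00  0.00           O",
    "END")
}

write_toy_pdb <- function(path, lines = toy_pdb_lines()) {
  writeLines(lines, path)
  path
}

# Build a structural_signature by hand (for alignment worked examples).
fixture_signature <- function(coords, atom_freq, res_freq, preservation,
                              n_structures = 10L, cutoff = 0.5,
                              polarity = "positive") {
  P <- nrow(coords)
  sig <- structure(list(
    drug_id = "fix", polarity = polarity,
    positions = data.frame(index = seq_len(P), x = coords[, 1],
                           y = coords[, 2], z = coords[, 3],
                           preservation = preservation,
                           support = as.integer(round(preservation * n_structures))),
    atom_freq = atom_freq, res_freq = res_freq,
    n_structures = n_structures, preservation_cutoff = cutoff,
    params = unclass(scoring_params())
  ), class = "structural_signature")
  pocketsig:::validate_signature(sig)
  sig
}
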
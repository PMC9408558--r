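# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# fixed-column PDB ATOM line
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", ins = " ", altloc = " ") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resno, ins,
          x, y, z, 1, 0, substr(trimws(name), 1, 1))
}

# minimal n-residue CA-only single-chain PDB text
mini_pdb_text <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                          resname = "ALA", serial0 = 0L) {
  resname <- rep(resname, length.out = nrow(xyz))
  c(vapply(seq_len(nrow(xyz)), function(i)
    pdb_atom_line(serial0 + i, "CA", resname[i], chain, resno[i],
                  xyz[i, 1], xyz[i, 2], xyz[i, 3]), ""),
    "TER", "END")
}

# the same content in mmCIF dialect
mini_cif_text <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                          resname = "ALA") {
  resname <- rep(resname, length.out = nrow(xyz))
  c("data_mini", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
             "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
    sprintf("ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s CA 1",
            seq_len(nrow(xyz)), resname, chain, seq_len(nrow(xyz)),
            xyz[, 1], xyz[, 2], xyz[, 3], resno, resname, chain))
}

write_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small deterministic protein-like CA cloud
fixture_xyz <- function(n, seed = 42) {
  set.seed(seed)
  steps <- matrix(rnorm(n * 3), n, 3)
  steps <- steps / sqrt(rowSums(steps^2))
  apply(3.8 * steps, 2, cumsum)
}

# CA-only abc_structure straight from coordinates
structure_from_xyz <- function(xyz, chain = "A", entry_id = "fix",
                               resno = seq_len(nrow(xyz)),
                               label_seq = NULL) {
  at <- data.frame(chain = chain, resno = resno, resname = "ALA",
                   atom = "CA", x = xyz[, 1], y = xyz[, 2],
                   z = xyz[, 3], stringsAsFactors = FALSE)
  if (!is.null(label_seq)) at$label_seq <- label_seq
  abc_structure(at, entry_id = entry_id)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)
}

# brute-force rigid-superposition oracle: coarse-to-fine search over ZYZ
# Euler angles with the centroid-matching translation, independent of the
# SVD route it checks
brute_force_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  euler <- function(a, b, g) {
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    rot_z(a) %*% Ry %*% rot_z(g)
  }
  eval_rmsd <- function(a, b, g)
    sqrt(mean(rowSums((Pc %*% t(euler(a, b, g)) - Qc)^2)))
  best <- c(0, 0, 0); best_v <- eval_rmsd(0, 0, 0)
  step <- 6 * pi / 180
  grid <- list(a = seq(0, 2 * pi, by = step),
               b = seq(0, pi, by = step),
               g = seq(0, 2 * pi, by = step))
  for (a in grid$a) for (b in grid$b) for (g in grid$g) {
    v <- eval_rmsd(a, b, g)
    if (v < best_v) { best_v <- v; best <- c(a, b, g) }
  }
  for (step2 in c(0.5, 0.05, 0.005) * pi / 180) {
    rng <- 12 * step2
    for (a in seq(best[1] - rng, best[1] + rng, by = step2))
      for (b in seq(best[2] - rng, best[2] + rng, by = step2))
        for (g in seq(best[3] - rng, best[3] + rng, by = step2)) {
          v <- eval_rmsd(a, b, g)
          if (v < best_v) { best_v <- v; best <- c(a, b, g) }
        }
  }
  best_v
}
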
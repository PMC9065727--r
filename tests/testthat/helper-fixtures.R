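# Fixtures built in code: tiny PDB texts and reusable synthetic objects.

pdb_atom_line <- function(serial, name, resname, resno, x, y, z,
                          occ = 1, alt = "") {
  sprintf("ATOM  %5d  %-3s%1s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resname, resno, x, y, z, occ, 0)
}

# one-residue PDB with explicit backbone + amide H
write_mini_pdb <- function(path) {
  writeLines(c(
    pdb_atom_line(1, "N", "ALA", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", 1, 1.458, 0, 0),
    pdb_atom_line(3, "C", "ALA", 1, 2.009, 1.420, 0),
    pdb_atom_line(4, "O", "ALA", 1, 3.232, 1.536, 0),
    pdb_atom_line(5, "H", "ALA", 1, 0, 0, 1.02),
    "END"), path)
  path
}

# three translated copies of a 3-atom residue as MODEL blocks
write_multimodel_pdb <- function(path) {
  lines <- character(0)
  for (m in 1:3) {
    lines <- c(lines, sprintf("MODEL     %4d", m),
               pdb_atom_line(1, "N", "GLY", 1, 0 + m, 0, 0),
               pdb_atom_line(2, "CA", "GLY", 1, 1.458 + m, 0, 0),
               pdb_atom_line(3, "C", "GLY", 1, 2.009 + m, 1.42, 0),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# altloc fixture: CA has A (occ 0.30) and B (occ 0.70); N has tied A/B
write_altloc_pdb <- function(path) {
  writeLines(c(
    pdb_atom_line(1, "N", "ALA", 1, 0, 0, 0, occ = 0.5, alt = "A"),
    pdb_atom_line(2, "N", "ALA", 1, 9, 9, 9, occ = 0.5, alt = "B"),
    pdb_atom_line(3, "CA", "ALA", 1, 1, 1, 1, occ = 0.3, alt = "A"),
    pdb_atom_line(4, "CA", "ALA", 1, 2, 2, 2, occ = 0.7, alt = "B"),
    pdb_atom_line(5, "C", "ALA", 1, 3, 3, 3),
    "END"), path)
  path
}

# random rotation matrix (uniform via QR of Gaussian)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion to every atom of a structure_model
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(rotation), 2, translation, "+")
  model$atoms$x <- moved[, 1]
  model$atoms$y <- moved[, 2]
  model$atoms$z <- moved[, 3]
  model
}

# brute-force coupling for one unit vector and tensor: rotate the vector
# into the tensor PAS and evaluate the axial/rhombic angular expression
brute_force_rdc <- function(tensor, v) {
  R <- euler_zyz(tensor$euler[1], tensor$euler[2], tensor$euler[3])
  w <- as.numeric(t(R) %*% v)
  ct2 <- w[3]^2
  st2 <- 1 - ct2
  phi <- atan2(w[2], w[1])
  tensor$da * ((3 * ct2 - 1) +
                 1.5 * tensor$rhombicity * st2 * cos(2 * phi))
}

random_unit_vectors <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m <- m / sqrt(rowSums(m^2))
  data.frame(resno = seq_len(n), x = m[, 1], y = m[, 2], z = m[, 3])
}

as_nh <- function(df) {
  class(df) <- c("nh_vectors", "data.frame")
  df
}
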
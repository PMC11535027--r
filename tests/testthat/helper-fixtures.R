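# Programmatic fixtures: everything is built in code at test time.

pdb_atom_line <- function(serial, name, resname, resno, x, y, z,
                          element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, resno, x, y, z, element)
}

# Two-residue fixture: residue 2 has N at origin and H at 1.02 A along +z.
write_two_residue_pdb <- function(path, with_H = TRUE) {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", 1, 0, 0, -3),
    pdb_atom_line(2, "CA", "ALA", 1, 1.3, 0, -3),
    pdb_atom_line(3, "C", "ALA", 1, 2.2, 0, -2),
    pdb_atom_line(4, "O", "ALA", 1, 3.2, 0, -2),
    pdb_atom_line(5, "N", "GLY", 2, 0, 0, 0),
    if (with_H) pdb_atom_line(6, "H", "GLY", 2, 0, 0, 1.02),
    pdb_atom_line(7, "CA", "GLY", 2, 1.2, 0.8, 0),
    "END"
  )
  writeLines(lines[!vapply(lines, is.null, logical(1))], path)
  path
}

# Ideal-geometry alpha-helix backbone (N, H, CA, C) for n residues.
write_helix_pdb <- function(path, n = 10) {
  lines <- character(0)
  serial <- 0
  add <- function(name, resno, xyz) {
    serial <<- serial + 1
    lines <<- c(lines, pdb_atom_line(serial, name, "ALA", resno,
                                     xyz[1], xyz[2], xyz[3]))
  }
  for (i in seq_len(n)) {
    phi <- (i - 1) * 100 * pi / 180   # ~100 deg per residue
    zi <- (i - 1) * 1.5
    nc <- c(2.3 * cos(phi), 2.3 * sin(phi), zi)
    add("N", i, nc)
    # H pointing outward from the helix axis
    add("H", i, nc + 1.02 * c(cos(phi), sin(phi), 0))
    add("CA", i, c(2.3 * cos(phi + 0.5), 2.3 * sin(phi + 0.5), zi + 0.5))
    add("C", i, c(2.3 * cos(phi + 1.0), 2.3 * sin(phi + 1.0), zi + 1.0))
  }
  writeLines(c(lines, "END"), path)
  path
}

make_shift_table <- function(residues, h, x, x_nucleus = "15N",
                             atom = "N-H") {
  dplyr::bind_rows(
    tibble::tibble(residue = residues, atom = atom, nucleus = "1H",
                   shift_ppm = h),
    tibble::tibble(residue = residues, atom = atom, nucleus = x_nucleus,
                   shift_ppm = x)
  )
}

# Independent rigid-rotor 15N rate oracle (dipolar + CSA, single Lorentzian),
# written directly from the textbook expressions; used to cross-check
# predict_rates at S2 = 1.
rigid_rates_oracle <- function(tau_c, B0, r_NH = 1.02e-10, csa = -172e-6) {
  gH <- 2.6752218744e8; gN <- -2.7126e7
  hbar <- 1.054571817e-34; mu0_4pi <- 1e-7
  wH <- gH * B0; wN <- gN * B0
  J <- function(w) 0.4 * tau_c / (1 + (w * tau_c)^2)
  d <- mu0_4pi * hbar * gH * gN / r_NH^3
  c2 <- (abs(wN) * csa)^2 / 3
  R1 <- d^2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- d^2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                     6 * J(wH + wN)) + c2 / 6 * (4 * J(0) + 3 * J(wN))
  noe <- 1 + d^2 / 4 * (gH / gN) * (6 * J(wH + wN) - J(wH - wN)) / R1
  list(R1 = R1, R2 = R2, noe = noe)
}
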
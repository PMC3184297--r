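# Hand-constructed PDB text fixtures, built in code.

pdb_atom_line <- function(serial, name, resname, resno, x, y, z,
                          altloc = " ", occ = 1.00, chain = "A") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          serial, name, altloc, resname, chain, resno, x, y, z, occ,
          substr(name, 1, 1))
}

# Two alanines with printable coordinates.
two_residue_pdb <- function(extra_cb = FALSE) {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", 1, 0.000, 1.460, 0.000),
    pdb_atom_line(2, "CA", "ALA", 1, 0.000, 0.000, 0.000),
    pdb_atom_line(3, "C", "ALA", 1, 1.490, -0.500, 0.000),
    pdb_atom_line(4, "N", "ALA", 2, 2.400, 0.400, 0.000),
    pdb_atom_line(5, "CA", "ALA", 2, 3.800, 0.100, 0.100),
    pdb_atom_line(6, "C", "ALA", 2, 4.700, 1.300, 0.300)
  )
  if (extra_cb)
    lines <- append(lines, pdb_atom_line(7, "CB", "ALA", 2, 4.200, -0.800, 1.000))
  c(lines, "TER", "END")
}

# Five glycines along x; residue 3 lacks its C atom.
five_residue_missing_c_pdb <- function() {
  lines <- character(0)
  serial <- 0
  for (r in 1:5) {
    base <- (r - 1) * 3.8
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "N", "GLY", r, base, 1.46, 0))
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "CA", "GLY", r, base, 0, 0))
    if (r != 3) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(serial, "C", "GLY", r, base + 1.49, -0.5, 0))
    }
  }
  c(lines, "END")
}
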
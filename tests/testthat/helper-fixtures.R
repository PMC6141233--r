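# shared fixtures for the test suite

# control-fiber parameters of the three-process modulus model; amplitudes in
# kN/m^2, characteristic frequencies chosen so the apparent rate constants
# are 2*pi*b = 1036 and 2*pi*c = 5376 s^-1
control_nyquist <- function() {
  nyquist_params(A = 339, k = 0.12, alpha = 1,
                 B = 741, b = 1036 / (2 * pi),
                 C = 923, c = 5376 / (2 * pi))
}

# 50 log-spaced oscillation frequencies spanning the bench protocol
protocol_frequencies <- function(n = 50, lo = 0.5, hi = 650) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# noiseless forward-model spectrum at the protocol frequencies
control_spectrum <- function(amplitude = 0.00125) {
  f <- protocol_frequencies()
  y <- eval_nyquist(control_nyquist(), f)
  modulus_spectrum(f, Re(y), Im(y), amplitude = amplitude)
}

# minimal fixed-width PDB ATOM record
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, elety, resid, chain, resno, x, y, z)
}

# write a synthetic PDB file from a data frame of atoms
write_synthetic_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- mapply(pdb_atom_line, seq_len(nrow(atoms)), atoms$elety,
                  atoms$resid, atoms$chain, atoms$resno,
                  atoms$x, atoms$y, atoms$z)
  writeLines(c(lines, "END"), path)
  path
}

# default ensemble parameters used across simulator tests: moderate duty
# ratio, stiffness and stroke in the single-molecule range
test_bridge_params <- function(...) {
  args <- list(n_bridges = 2000, f_att = 300, g_det0 = 1000,
               kappa = 2, d_stroke = 8, sarcomere_area = 1e6)
  args[names(list(...))] <- list(...)
  do.call(crossbridge_params, args)
}
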
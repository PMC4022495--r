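# Shared fixtures, built once per test run (generators are deterministic).

.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fx_cache)) assign(key, builder(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

fx_peptides <- function() cached("peptides", make_ideal_peptide_fixtures)

fx_monomer <- function() cached("monomer", function()
  make_two_lobe_monomer(list(n_res_per_lobe = 30, linker_length = 5,
                             helix_tail_length = 10, seed = 1)))

fx_dimer <- function() cached("dimer", function() make_swapped_dimer(fx_monomer()))

# one-off atom-table structures for contact toys
toy_atoms <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r$chain, resno = r$resno, insert = "",
               resid = r$resid, elety = r$elety,
               elesy = substr(trimws(r$elety), 1, 1),
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               o = 1, b = 0, alt = "", het = isTRUE(r$het),
               stringsAsFactors = FALSE)))
  protein_structure(df, id = "toy")
}

atomr <- function(chain, resno, resid, elety, xyz, het = FALSE)
  list(chain = chain, resno = resno, resid = resid, elety = elety,
       xyz = xyz, het = het)

atom_xyz_of <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

random_rotation <- function() {
  # uniform-ish random rotation from a normalized quaternion
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotation_angle_between <- function(R1, R2) {
  # angle of R1 R2^T via ||R - I||_F = 2*sqrt(2)*|sin(angle/2)|; well
  # conditioned near zero, unlike the trace/acos form
  R <- R1 %*% t(R2)
  fn <- sqrt(sum((R - diag(3))^2))
  2 * asin(min(1, fn / (2 * sqrt(2)))) * 180 / pi
}
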
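# Shared fixtures: all built in code, no stored binaries.

# A bare charged sphere ("ion") for closed-form electrostatics/SASA oracles.
make_ion <- function(q = 1, pos = c(0, 0, 0), radius = 2.0, id = "ion") {
  molecule(id, data.frame(name = "ION", element = "X", resname = "ION",
                          resid = 1, x = pos[1], y = pos[2], z = pos[3],
                          charge = q, radius = radius, hbond_role = "none",
                          stringsAsFactors = FALSE),
           net_charge = if (abs(q - round(q)) < 1e-12)
             as.integer(round(q)) else NA_integer_)
}

# Born solvation free energy of a sphere of radius a (Angstrom) moved from
# dielectric e1 into e2, in kJ/mol.
born_energy <- function(a, e1, e2, q = 1) {
  -energy_constants()$coulomb * q^2 / (2 * a) * (1 / e1 - 1 / e2)
}

# Analytic SASA of two equal intersecting spheres of expanded radius R at
# centre distance d: each sphere loses a cap of height R - d/2.
two_sphere_sasa <- function(R, d) 4 * pi * R * (R + d / 2)

# Minimal two-atom molecule with explicit roles, for H-bond fixtures.
make_polar_atom <- function(name, element, pos, role, resname = "FIX",
                            resid = 1) {
  data.frame(name = name, element = element, resname = resname,
             resid = resid, x = pos[1], y = pos[2], z = pos[3],
             charge = 0, radius = 1.5, hbond_role = role,
             stringsAsFactors = FALSE)
}
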
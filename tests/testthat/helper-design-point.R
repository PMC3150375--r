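# Reference design point used throughout the suite: 250 x 1250 x 13000 um
# chamber perfused at 33 uL/hr, a ~20 kDa ligand at D = 1e-6 cm2/s, and a
# floor of cells with 1e4 receptors (k_on = 1e6 /M/s) over a 10 um disc.
design_geom <- function() chamber_geometry(250, 1250, 13000)
design_setting <- function() perfusion_setting(33, 1e-3)
design_ligand <- function() ligand_spec(20, 1e-6)
design_receptor <- function() receptor_spec(1e6, 1e4, 10)

# Coarse grid for fast solver tests; default grid reserved for the deeper
# acceptance checks.
coarse_grid <- function(nx = 131, nz = 26) grid2d(design_geom(), nx, nz)
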
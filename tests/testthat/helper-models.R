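# shared small fixtures, built in code

reference_table1 <- function() {
  rbind(
    data.frame(theta_deg = 30, ctn = 0:5,
               dp_pa = c(81.5, 115, 159, 205, 244, 285)),
    data.frame(theta_deg = 60, ctn = 0:5,
               dp_pa = c(81.5, 107, 137, 166, 196, 228)),
    data.frame(theta_deg = 90, ctn = 0:5,
               dp_pa = c(81.5, 101, 121, 145, 167, 187)),
    data.frame(theta_deg = 120, ctn = 0:5,
               dp_pa = c(81.5, 92.7, 104, 116, 127, 139))
  )
}

# short straight channel mesh for cheap solver tests (SI-consistent with the
# default fluid/bc)
short_channel_mesh <- function(L = 20, d = 3, interval = 1) {
  path <- build_centerline(vessel_geometry(theta_deg = 30, n = 0, L = L,
                                           d = d))
  sweep_mesh(offset_lumen(path, d), interval)
}

design_grid <- function() {
  expand.grid(theta_deg = c(30, 60, 90, 120), n = 0:5)
}
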
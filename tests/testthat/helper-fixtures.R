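# Shared fixtures built in code.

# Annotation tibble for one or more cilia given endpoint coordinates.
make_annotation <- function(id, x, y, z_first, z_last) {
  tibble::tibble(
    cilium_id = id,
    point_index = seq_along(x) - 1L,
    x = x, y = y,
    z_first = z_first, z_last = z_last
  )
}

# Independent ICC(A,1) oracle: mean squares from R's own ANOVA machinery
# on the melted two-way layout (distinct code path from the package's
# closed-form mean-square computation).
icc_a1_oracle <- function(a, b) {
  n <- length(a)
  df <- data.frame(
    y = c(a, b),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(c("A", "B"), each = n))
  )
  aov_tab <- anova(stats::lm(y ~ subject + rater, data = df))
  msr <- aov_tab["subject", "Mean Sq"]
  msc <- aov_tab["rater", "Mean Sq"]
  mse <- aov_tab["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Render a single noise-free cilium and return stack + annotations.
render_clean <- function(L, elevation, azimuth = 30) {
  render_cilium_stack("c1", L, elevation, azimuth,
    cfg = render_config(noise_sd = 0), noise_seed = 1
  )
}

# Write a small OME-TIFF (grayscale, with PhysicalSize metadata) using the
# system Python's tifffile; returns the path.
write_ome_fixture <- function(path, nz = 3, ny = 4, nx = 5,
                              dxy = 0.1, dz = 0.25) {
  script <- sprintf(paste0(
    "import numpy as np, tifffile\n",
    "a = np.arange(%d*%d*%d, dtype=np.uint8).reshape(%d, %d, %d)\n",
    "tifffile.imwrite(r'%s', a, photometric='minisblack', description=",
    "'<OME xmlns=\"http://www.openmicroscopy.org/Schemas/OME/2016-06\">",
    "<Image><Pixels PhysicalSizeX=\"%g\" PhysicalSizeZ=\"%g\"/>",
    "</Image></OME>')\n"
  ), nz, ny, nx, nz, ny, nx, path, dxy, dz)
  status <- system2("python", c("-c", shQuote(script)),
    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  path
}
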
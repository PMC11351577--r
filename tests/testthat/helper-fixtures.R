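# Shared fixtures: a small phantom dataset plus extracted features, built
# once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

phantom_fixture <- function(n_subjects = 24L, seed = 42L) {
  key <- sprintf("ph_%d_%d", n_subjects, seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  dir <- file.path(tempdir(), paste0("qlung_fix_", key))
  cfg <- phantom_config(n_subjects = n_subjects, seed = seed)
  manifest <- generate_phantom_dataset(cfg, dir)
  bb <- tiny_cnn_backbone(seed = 2L)
  feats <- extract_dataset_features(bb, manifest)
  fix <- list(dir = dir, config = cfg, manifest = manifest, backbone = bb,
              cxr = feats$CXR, ct = feats$CT)
  .fixture_env[[key]] <- fix
  fix
}

# Write a tiny PNG from a matrix of 8-bit gray values (or an RGB array).
write_test_png <- function(values, path = tempfile(fileext = ".png")) {
  png::writePNG(values / 255, target = path)
  path
}
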
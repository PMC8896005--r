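# Shared fixtures. The default synthetic bundle and its pipeline run are
# generated once per session and reused across test files.

.fixtureCache <- new.env(parent = emptyenv())

# a scaled-down configuration for fast closed-loop tests
smallSynthConfig <- function(seed = 5, ...) {
  lib <- data.frame(
    type = c("TcA", "HelA", "LineA"),
    family = c("Tc1/mariner", "Helitron", "CR1"),
    repeat_class = c("DNA", "RC", "LINE"),
    mean_len = c(400, 350, 300),
    copies = c(16, 10, 8), stringsAsFactors = FALSE)
  plan <- data.frame(te_type = c("TcA", NA, NA),
                     fold = c(12, NA, NA),
                     n_planted = c(80L, 40L, 30L),
                     outside_only = c(FALSE, FALSE, TRUE))
  synthConfig(seed = seed,
              chromLengths = c(chrI = 120000L, chrII = 120000L),
              teLibrary = lib, nMotifs = 3, plan = plan,
              domProbRange = c(0.95, 0.99),
              nGenes = 50, atacNoise = 60, chipNoise = 120,
              chromLengthsB = c(cbI = 60000L, cbII = 60000L),
              teLibraryB = data.frame(
                type = c("TcB", "HelB"),
                family = c("Tc1/mariner", "Helitron"),
                repeat_class = c("DNA", "RC"),
                mean_len = c(350, 300), copies = c(8, 6),
                stringsAsFactors = FALSE),
              nGenesExtraB = 10,
              ortho = list(n = 40, K = 10, n_b = 9, k = 7, motif = 3,
                           similarFrac = 0.4, boundFrac = 0.5), ...)
}

# default-scale bundle + pipeline run, computed once
sharedRun <- function() {
  if (!is.null(.fixtureCache$run)) return(.fixtureCache$run)
  dir <- file.path(tempdir(), "temotifs-shared")
  cfg <- synthConfig(seed = 101)
  bundle <- suppressWarnings(suppressMessages(
    generateBundle(cfg, file.path(dir, "bundle"))))
  res <- suppressWarnings(suppressMessages(
    runPipeline(file.path(dir, "bundle"), file.path(dir, "out"),
                runConfig(accessMinSites = 50, accessMinPct = 10,
                          boundMinRegions = 100, boundMinPct = 5))))
  .fixtureCache$run <- list(dir = dir, config = cfg, bundle = bundle,
                            res = res)
  .fixtureCache$run
}

# small-scale closed-loop run (high-information motifs, so chance hits are
# essentially absent and scan output equals the planted ground truth)
smallRun <- function() {
  if (!is.null(.fixtureCache$small)) return(.fixtureCache$small)
  dir <- file.path(tempdir(), "temotifs-small")
  cfg <- smallSynthConfig()
  bundle <- suppressWarnings(suppressMessages(
    generateBundle(cfg, file.path(dir, "bundle"))))
  res <- suppressWarnings(suppressMessages(
    runPipeline(file.path(dir, "bundle"), file.path(dir, "out"),
                runConfig(minTeBp = 2000, minFold = 8,
                          accessMinSites = 20, accessMinPct = 10,
                          boundMinRegions = 50, boundMinPct = 5))))
  .fixtureCache$small <- list(dir = dir, config = cfg, bundle = bundle,
                              res = res)
  .fixtureCache$small
}
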
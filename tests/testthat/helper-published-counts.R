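# Read counts reported for the original validation sequencing runs, used to
# check that the package's reporting math reproduces the published
# percentage columns. Species order follows the community recipe order of
# builtin_communities().

# Broad mollusc assay, five mock communities (run with the fish blocker).
MC_READS <- list(
  MC1 = c(138075, 85010, 13, 1385, 195, 23002, 59973, 5594, 6235, 711, 99),
  MC2 = c(3745, 2174, 0, 42, 149359, 2536, 5166, 565, 783, 9513, 12),
  MC3 = c(885, 341, 0, 112573, 15359, 800, 2686, 209, 31795, 2654, 13),
  MC4 = c(773, 244, 2679, 116994, 17620, 1794, 4872, 43807, 67309, 5921, 84),
  MC5 = c(30, 163825, 63, 2199, 331, 246, 33459, 3752, 4494, 536, 26))

# Sphaeriid assay runs (communities 1, 2 and 4); three sphaeriid species.
SPH_READS <- list(
  MC1 = c(`Sphaerium similie` = 108760, `Sphaerium corneum` = 551,
          `Pisidium compressum` = 17),
  MC2 = c(`Sphaerium similie` = 1461, `Sphaerium corneum` = 16,
          `Pisidium compressum` = 100190),
  MC4 = c(`Sphaerium similie` = 500, `Sphaerium corneum` = 82990,
          `Pisidium compressum` = 6502))

# Walleye observed percentage with / without the fish blocking primer
# (communities 3 and 4, plus the preliminary trial with ~41% fish DNA).
WALLEYE_BLOCKING <- data.frame(
  sample = c("MC3", "MC4", "trial"),
  pct_with = c(0.000, 1.022, 15.380),
  pct_without = c(0.001, 8.717, 41.194))

# Aquarium tank A, broad assay: per-OTU read counts identified at >= 97%
# identity (first entry is the dominant fingernail clam OTU).
TANK_A_READS <- c(25707, 3037, 235, 218, 132, 117, 74, 56, 52, 10)

# Filtration blank: one 63-read contaminant OTU plus eight singleton reads.
BLANK_OTU_READS <- 63
BLANK_N_SINGLETONS <- 8
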
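# The seeded default cohort used by the comparative-ranking and
# sensitivity-stability checks. Run once per test session and shared.

.cohortCache <- new.env(parent = emptyenv())

cohortFixture <- function() {
  if (is.null(.cohortCache$study)) {
    .cohortCache$study <- runStudy(studyConfig(seed = 1), verbose = FALSE)
  }
  .cohortCache$study
}
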
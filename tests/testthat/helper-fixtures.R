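# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

cdParams <- function() referenceParams("CD")

cdProtocol <- function() infusionProtocol("clamp", bodyWeight = 25,
                                          initialRate = 0.15)

# noise-free CD clamp trajectory (closed loop)
cdClampTraj <- function() fixture("cdClampTraj", function()
  runClamp(cdParams(), cdProtocol()))

# noise-free CD record with exact (unrounded) doses
cdRecordExact <- function() fixture("cdRecordExact", function()
  simulateRecord(cdParams(), cdProtocol(), roundDoses = FALSE))

# noise-free CD record with pump-log rounding, as the cohort generator
# would emit
cdRecordRounded <- function() fixture("cdRecordRounded", function()
  simulateRecord(cdParams(), cdProtocol(), roundDoses = TRUE))

# a tiny two-mouse cohort for IO round-trips
tinyCohort <- function() fixture("tinyCohort", function() {
  g <- stGclamp:::.defaultGroupTable()[1, ]
  g$n <- 2L
  generateCohort(cohortSpec(groups = g, seed = 5L))
})
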
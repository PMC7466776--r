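Package: ivmux
Title: Multiplex Intravenous Infusion Scheduling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Schedules the alternating administration of chemically
    incompatible intravenous drugs through a single catheter lumen
    ("multiplex infusion"). Compatible drugs are grouped into infusion
    packets whose repetition periods are derived from each drug's maximal
    pharmacokinetic interruption time; packets are timed by non-preemptive
    earliest-deadline-first scheduling under a utilization-bound feasibility
    test, with burst administration rates that conserve hourly delivered
    volume and explicit separator-fluid accounting. Also models the
    conventional category-based lumen assignment procedure used by ICU
    nurses, and provides a synthetic patient-hour cohort generator plus an
    evaluation harness comparing lumen requirements of the two strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
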
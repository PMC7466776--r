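---
title: "Multiplex infusion scheduling: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex infusion scheduling: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmux)
```

## The problem

ICU patients commonly receive several continuous intravenous drugs at once.
Many of these solutions are chemically incompatible at the Y-site, so they
must not mix in shared tubing, and conventionally each incompatible group
needs its own catheter lumen. When lumens run out, extra peripheral
catheters are placed, with the attendant infection and phlebitis risk.

Multiplex infusion avoids this by *time-sharing* one lumen: incompatible
solutions are administered in alternating bursts ("infusion packets"),
separated by a flush of a mutually compatible separator fluid. The price is
pharmacokinetic: interrupting a drug for too long lets its plasma
concentration drift out of range. The tolerable gap is drug-specific — the
maximal interruption time, `T_iMax`, derived from population-PK simulation
and expert review and stored in the drug catalog. Drugs with very short
half-lives (norepinephrine and the other titrated pressors) tolerate no
interruption at all and are excluded from multiplexing outright.

`ivmux` implements both the multiplex scheduler and the conventional
nurse procedure it is compared against, plus a synthetic cohort generator
and an evaluation harness, so the whole comparison runs without access to
any clinical dataset.

## The scheduling model

**Packets.** Mutually compatible multiplexable drugs are grouped into
packets. Each packet slot administers its drugs simultaneously for
`d_drugs` minutes and then flushes for `d_sep` minutes, so the slot
duration is `D = d_drugs + d_sep`. A packet inherits the *smallest*
`T_iMax` of its members, which protects every member. Packets are formed to
be as few as possible (fewer packets mean fewer alternations and lower
lumen-time demand): for up to 12 drugs the package computes the exact
minimum clique partition of the compatibility graph by a memoized subset
recursion — order sets average about three drugs, so this is the production
path — and falls back to a greedy first-fit over drugs sorted by
decreasing `T_iMax` for larger sets.

**Periods and deadlines.** A packet with slot duration `D` and interruption
bound `T_iMax` repeats with period

```
P = D + T_iMax / 2.
```

If every slot lands somewhere inside its own period, two consecutive slots
are at most `2 (P - D) = T_iMax` apart, so deadline satisfaction implies
the PK constraint. The end of each period is the slot's deadline.

**Utilization.** The fraction of lumen time the packet set demands is
`U = sum(D_i / P_i)`. `U <= 1` is necessary for schedulability; because
scheduling here is non-preemptive it is not sufficient, so the dispatcher
also reports an explicit feasibility flag.

```{r}
utility(list(packet_dp(2, 3), packet_dp(1, 4)))
```

**Dispatching.** Slots are laid out by non-preemptive earliest-deadline-
first: whenever the lumen frees up, the released slot with the nearest
deadline runs to completion. Equal deadlines prefer the lower packet index.
A fixed tie-break alone can manufacture misses that another equally valid
EDF choice avoids (non-preemptive EDF is optimal among work-conserving
schedules as a class, not per tie-break), and since schedules are computed
before execution rather than in real time, the dispatcher backtracks across
equal-deadline choices before declaring a set infeasible. The search is
capped at 50,000 nodes; an instance still unresolved at the cap is reported
infeasible.

```{r}
tl <- edf_schedule(list(packet_dp(5, 20, "A"), packet_dp(5, 30, "B"),
                        packet_dp(10, 20, "C")))
head(as.data.frame(tl), 3)   # runs A, then C, then B
```

**Rates.** A drug that conventionally runs continuously at `Q_CONV` ml/h
but is only administered `a` minutes per hour must run at
`Q_MX = Q_CONV * 60 / a` during its slots to deliver the same hourly
volume; with the long-run average of `60 / P` runs per hour,
`a = d_drugs * 60 / P`. `Q_MX` is checked against the drug's maximal
administration rate converted to ml/h through its concentration (running
exactly at the maximum is allowed). Hourly volume conservation holds by
construction and is asserted on every pipeline output.

**Separator fluid.** Every slot ends with one flush of the separator
volume, by rule of thumb twice the shared infusion volume of the tube
(default 2 ml SIV, 4 ml flush; the experimentally measured 3.7 ml flush for
the same tube is available as a preset). The daily separator budget is the
number of slot runs per day times the flush volume.

## The pipeline and demotion

`schedule_multiplex()` follows a demotion loop: non-multiplexable and
unknown drugs go straight to the conventional scheduler; while `U > 1` the
drug with the smallest `T_iMax` is demoted and the survivors re-packetized
from scratch (re-packetizing can merge survivors); an EDF miss despite
`U <= 1` demotes the same way (rare, and logged); any drug whose burst rate
exceeds its maximum is demoted and the loop restarts. Each iteration
strictly shrinks the multiplexed set, so the loop terminates. Demoted and
non-multiplexable drugs are assigned lumens by the conventional four-stage
nurse procedure (vasoactive lumen, analgo-sedation lumens, dedicated
lumens, everything else; strict stages, alphabetical first-fit within a
stage).

Finally the plan is compared against scheduling *all* drugs conventionally.
Demotion can split drugs that conventionally share a lumen, so in corner
cases the assembled multiplex plan would need more lumens than doing
nothing; the scheduler then falls back to the conventional assignment
(reason `fallback_conventional`). A deployed scheduler always takes the
cheaper plan, and this guarantee makes the lumen reduction
`delta_l = l_conv - l_mx` nonnegative by construction.

```{r}
cat_ <- default_catalog()
chart <- default_compat()
res <- schedule_multiplex(infusion_orders(c("propofol", "vancomycin",
                                            "midazolam", "insulin"),
                                          c(10, 4, 3, 2)),
                          cat_, chart, quiet = TRUE)
res
```

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `d_drugs` | 5 | min | drug administration time per slot; 1, 2, 5, 10, 20 are the studied values and 5 best suits clinical constraints (pump start-up error dominates below ~2 min) |
| `d_sep` | 1 | min | separator flush time; sufficient for a 4 ml flush given syringe pumps that run up to 500 ml/h |
| SIV | 2 | ml | shared infusion volume of a standard 2 m tube |
| SFV | 2 × SIV | ml | separator volume per flush |
| `resolution_s` | 1 | s | scheduling grid; periods `D + T_iMax / 2` with odd integer `T_iMax` are half-minutes, which seconds represent exactly |

Lower `d_drugs` admits drugs with short `T_iMax` but multiplies
alternations (more separator fluid) and compresses burst rates toward the
maxima; higher `d_drugs` saves separator fluid but squeezes out
short-`T_iMax` drugs through the utilization bound.

## Numerical and degenerate-input choices

Time is handled internally in integer seconds, so hyperperiods (least
common multiples of the periods) are exact with no floating-point drift. A
period not representable on the grid is a resolution error. Catalog-derived
periods are often pairwise co-prime in seconds and their LCM can exceed any
practical horizon; when it exceeds 24 h the timeline is built, and
feasibility judged, over a 24 h scheduling horizon — the operational
horizon after which multiplex schedules are recomputed anyway (adding or
removing a fluid already triggers a fresh run) — while the true hyperperiod
is still reported. Unknown drugs are incompatible with everything and
non-multiplexable; insulin's undetermined multiplex suitability (tubing
adsorption) is treated as non-multiplexable. An all-zero set of sampling
weights, an empty order list, and a drug set with no multiplexable member
are validation errors or clean no-multiplex results, never crashes; a
comparison with constant lumen counts reports a degenerate regression
rather than failing.

## The synthetic cohort generator

The generator emulates the statistical shape of an ICU extract: per
patient-hour, the number of simultaneous drugs targets mean 2.8 and SD 1.6,
drawn as a rounded normal clamped to `[1, 34]`. Clamping shifts raw
moments (a raw 2.8/1.6 normal yields ≈ 2.90 after clamping), so the
generator treats the requested mean/SD as moments of the *clamped* count
distribution and solves for the latent normal parameters numerically; the
requested moments are then recovered within sampling error. Drugs are
sampled without replacement, uniformly by default, with an ICU-flavoured
skewed preset (`cohort_weights_preset()`) available. From hour to hour each
running drug persists with probability 0.75 (a compromise between
continuous sedation running for days and single-hour administrations); the
set is reconciled with the hour's drawn count, so with persistence 1 and a
fixed count a patient's set is frozen. Conventional rates are drawn from
clinically conventional per-category ranges (vasoactive 0.5–8,
analgo-sedation 1–10, other 1–6 ml/h) and clamped to each drug's
maximal-rate limit — actual rates sit well below the maxima, which is what
gives the multiplex algorithm its compression headroom.

What the generator does *not* emulate: real prescribing correlations
(antibiotic courses, weaning patterns), diurnal structure, bolus and
intermittent dosing, and a curated Y-site chart — the bundled compatibility
chart is a deterministic synthetic illustration (vasoactives mutually
compatible, analgo-sedation mutually compatible, antibiotics pairwise
incompatible, seeded coin flips elsewhere) with no clinical authority.
Passing tests therefore demonstrate the *algorithmic* properties
(conservation, interruption-bound safety, never needing more lumens than
conventional practice, qualitative direction of the savings), not clinical
effect sizes; the published effect sizes depend on the original 175,993
combination dataset and are out of reach by design.

## Evaluation statistics

`run_evaluation()` schedules every patient-hour both ways;
`summarize_evaluation()` reproduces the comparison layout: a per-level
table of `l_mx` against `l_conv` with reduction frequencies, the fraction
of all and of unique combinations (unique = unordered drug-name set) that
save at least one lumen, an OLS regression of `delta_l` on `l_conv`, and a
paired Wilcoxon signed-rank test (zeros dropped; exact null for ≤ 25
untied pairs, otherwise normal approximation with tie correction — lumen
counts are small integers, so the tie-corrected path is the practical one).
Daily aggregation takes per-day maxima of the hourly counts.

For the slot-duration sweep the separator metric is the mean daily
separator volume per *multiplexed* schedule (hours that actually use the
multiplex lumen). At `d_drugs = 1` the available administration time is so
short that long-`T_iMax` drugs with low volumetric maxima are necessarily
rate-demoted, which removes whole schedules from the multiplex pool; a
cohort-wide mean would confound the per-schedule trade-off with this
composition shift, while the per-schedule mean isolates the mechanism:
shorter slots, more alternations, more separator fluid.

The test suite exercises these claims at desk scale: a 2,000 patient-hour
cohort (100 patients × 20 h) for the qualitative replication, 1,000
randomized order sets for the safety and dominance properties, exhaustive
oracles (set-partition enumeration, work-conserving schedule enumeration,
sign-flip enumeration) on instances of up to 10 drugs, 4 packets, and 12
pairs respectively. These sizes are the package's chosen trade-off between
statistical resolution and a test suite that stays fast enough to run on
every change.

## Known limitations

* The published clinical effect sizes (27% of all / 61% of unique
  combinations improved, the fitted regression coefficients, the printed
  per-level table) are dataset-bound and are deliberately not asserted.
* Inserted-idle-time policies can beat work-conserving non-preemptive EDF
  on some instances; the dispatcher never idles deliberately.
* Pump start-up delays, dead-volume mixing dynamics, boluses, intermittent
  infusions, empty packets for CVP measurement, and mid-execution schedule
  edits are out of scope.
* `T_iMax` values are taken as catalog data; their PK derivation is not
  re-simulated here.
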
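---
title: "mobsense: models, conventions, and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mobsense: models, conventions, and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what the
pipeline computes, under which assumptions, which knobs matter, and where
the design was genuinely open and a choice had to be made. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The problem

Mobile-sensing studies produce per-device event logs (epoch-millisecond
UTC timestamps plus sensor-specific payloads) from phones, Fitbit, and
Empatica devices. The analysis-ready object is a *feature matrix*: one row
per (participant, time-segment instance), one column per behavioral
feature. Getting there requires localizing timestamps across time zones and
daylight-saving transitions, merging multiple devices per person,
reconstructing interval episodes from point events, windowing time
flexibly, and accounting for missing coverage. Each step embeds conventions
that silently change downstream statistics; this package fixes every such
convention explicitly, in one place.

## 2. Time conventions

Stated once, used everywhere:

* **Intervals are half-open `[start, end)`.** Windows tile without double
  counting; a row exactly on a boundary belongs to the later window.
* **Raw timestamps are UTC epoch milliseconds.** Conversion is UTC→local
  only, so nonexistent local times can never arise from row localization.
* **Local wall times** are carried as UTC-labeled `POSIXct` whose clock
  reads the wall time. This lets one column hold wall times from different
  zones and keeps wall-clock arithmetic exact.
* **Wall → UTC for segment boundaries**: the earliest UTC instant whose
  local reading reaches the boundary. During a spring-forward gap this is
  the transition instant, so a wall window swallowed by the gap has an
  empty UTC span (it can never contain data, but it still counts toward
  the `1440/length` frequency-window contract). During a fall-back fold it
  is the *first* occurrence, so both UTC instants of the repeated hour fall
  inside the same local segment — the daily segment on such a day spans 25
  real hours, and on a spring-forward day 23. Segment-relative quantities
  (data-yield denominators, `minsmissing`) use the real UTC span.
* **Frequency windows are defined in wall time**, not elapsed time. Whether
  a window straddling a DST transition should keep wall alignment or
  constant duration is genuinely underdetermined; wall time was chosen
  because it keeps windows aligned with the civil clock that structures
  human behavior, and it is flagged here.
* **Zone selection for a nominal date** (when a participant's time-zone
  history has several entries): the zone active at that date's UTC
  midnight. A traveler's switch day is thus attributed to one zone,
  deterministically.

## 3. Segments

Three families, from a plain CSV definition file:

* *frequency* — windows of `length` minutes (must divide 1440) tiling every
  study day from midnight;
* *periodic* — one window per matching day (`every_day`, day-of-week,
  -month, -quarter, -year) starting at a wall clock time, any length,
  midnight-spanning allowed. Multi-day summaries ("last 7 days") are
  expressed as periodic windows of `7d`-type lengths;
* *event* — anchored at per-participant event timestamps, shifted
  before/after; with direction `before` and shift 0, a 3 h window is
  `[t − 3h, t)`, matching the "window preceding a self-report" idiom.

Rows are assigned to every instance whose UTC interval contains them
(overlap means multiple assignment); assignment is order-stable and
idempotent.

## 4. Episodes

Event logs become interval episodes before feature extraction:

* **Screen sessions** — Android: unlock (3) to the next off (0); lock (2)
  events inside a session are ignored (a documented choice; the platforms
  do not specify it). iOS reports only lock/unlock, so sessions run
  unlock (3) to locked (2). A trailing unterminated unlock is closed at the
  last observed screen row and flagged `truncated`; a config switch drops
  flagged episodes instead (transparency over silent loss).
* **Battery** — maximal runs of non-increasing level are discharge episodes
  (so a constant level is a zero-drop discharge, rate 0), strictly
  increasing runs are charges; single-row runs carry no duration and are
  dropped. Rates are %/h over the run.
* **Activity bouts** — same-class runs, broken by gaps above 5 min
  (configurable); classes map to stationary/mobile/vehicle.
* **Sleep stages** — per-minute stage rows become maximal constant-stage
  episodes; classic-log `restless` maps to `light`, `asleep` stays its own
  stage.

Splitting intersects episodes with instances and conserves duration to the
millisecond — property-tested on 1,000 random configurations.

## 5. The feature catalog

The catalog registers 407 features (191 phone, 166 Fitbit, 50 Empatica)
across 35 providers. Per-sensor *counts* are the conformance contract and
are enforced at package load and in the acceptance suite. The *member
names and formulas* are this package's documented conventions; notable
fixed choices:

* `std` is always the sample standard deviation (n−1), `NA` for n < 2.
* Mode ties break to the smallest value; "most frequent contact/device/app"
  counts are tie-independent.
* Duration entropy (calls): Shannon entropy, natural log, weights
  `d_i / Σd`; 0 when the total is zero or n ≤ 1. Hence
  `entropy ∈ [0, ln n]`.
* Value entropy (Empatica, HR): Shannon entropy of the empirical
  distribution of values rounded to 2 decimals (continuous signals need
  discretization; the rounding is configurable).
* Time-of-day features are minutes since local midnight.
* Missing-data policy: a segment with zero rows keeps its row in the
  output with count-like features 0 and statistic-like features `NA`; a
  config switch (`drop_empty_rows`) drops such rows instead.
* Bluetooth ownership (extended provider): a device is "own" when its
  total scan count over the participant's whole input reaches 50% of the
  most-scanned device's count (`own_share`). Scan-frequency thresholding
  is the standard heuristic; the exact cutoff is a convention.
* The two location providers split 34 features as 18 (cluster-based) + 16
  (trajectory-based). Only the total is externally fixed; the split and
  membership are package conventions. Both providers run on any segment
  type; restricting one family to multi-day segments (as some upstream
  tools do) is left to study configuration.
* Fitbit summary providers (heart-rate 37, sleep 36, steps 5) and the
  calories/sleep-intraday catalogs (22, 21 + 13) are fixed member lists
  over daily summary records; counts are enforced at startup.

## 6. Mobility

* **Stationarity**: a point is moving when the segment speed from its
  predecessor exceeds 1 km/h (default).
* **Significant places**: DBSCAN over great-circle (haversine, R =
  6,371,000 m) distances on *stationary* points of the participant's whole
  history — whole-study clustering keeps cluster identities stable so
  "time at top-K place" is comparable across segments. Defaults eps =
  100 m, minPts = 5; the accuracy filter drops fixes worse than 100 m
  first. Clusters are ranked by dwell; dwell at a point is the gap to the
  next point capped at 10 min, so sampling holes do not inflate stays.
* **Radius of gyration**: `sqrt(Σ_c w_c · d(c, centroid_w)² / Σ_c w_c)`
  with dwell weights; equal dwell at two anchors distance D apart gives
  D/2 (the acceptance fixture).
* **Circadian movement**: log10 of the mean normalized Lomb–Scargle power
  of the latitude and longitude series in the 23.5–24.5 h period band
  (40 band frequencies). The least-squares periodogram tolerates the
  irregular sampling of real GPS traces; the test contract is ordinal (a
  24 h-periodic trace scores above its time-shuffle), so the base of the
  log and the band discretization are free conventions.
* **Flights and pauses**: stationary runs of at least 5 min are pauses;
  everything else (including sub-threshold stationary stretches) belongs
  to flights, whose length is the summed point-to-point path. `probpause`
  is pause time over covered time.
* **Routine indices** (`circdnrtn`, `wkenddayrtn`): mean pairwise cosine
  similarity between daily cluster-dwell vectors — all day pairs for the
  first, same-type pairs (weekend–weekend, weekday–weekday) for the
  second. They need ≥ 2 (matching) days inside one segment and are `NA`
  on daily segments; they are designed for multi-day windows.
* The trajectory provider operates on observed points only — no
  imputation of unobserved intervals; `minsmissing` exposes coverage
  instead. Imputation is a research choice this package deliberately does
  not make silently.

## 7. Data yield

`ratiovalidyieldedminutes` is the fraction of a segment's (real, UTC)
minutes containing at least one row from any configured sensor of the
device class; `ratiovalidyieldedhours` is the fraction of hours whose own
minute ratio reaches `hour_threshold` (default 0.5, the midpoint — an hour
is "monitored" if at least half its minutes are). Minute/hour bins are
anchored at the segment's UTC start; both ratios are clipped to [0, 1].
Researchers discard segments below their own validity threshold; the
package computes, it does not judge.

## 8. Pipeline

Stages are (participant × sensor × provider) feature computations, then
per-participant merges, a study merge, and the plots. A stage re-runs iff
the MD5 of any input file or its parameter fingerprint (canonical
serialization of the relevant config subtree) changed — content hashes,
not mtimes, so `touch` without change re-runs nothing and a restored file
re-validates. Downstream stages of a re-run stage re-run; failures skip
dependents only. Stages in one dependency level may run on several forked
workers; every stage writes only its own files, so outputs are
byte-identical for any worker count (CSV serialization is data.table's
deterministic `fwrite`, 15 significant digits).

The five QC plots are emitted as self-contained HTML with inline SVG and
hover tooltips — no external assets or JS dependencies, so reports open
anywhere. The correlation heatmap uses pairwise-complete Pearson (or
Spearman) correlation with a 30-row minimum overlap per pair.

## 9. The synthetic world

The generator's defaults are the package's stated reference conditions: 3
participants, 7 days starting 2020-03-04 (so the window straddles the US
spring-forward on 2020-03-08), one participant in America/New_York carrying
two phones switched mid-study, one participant losing all device data from
12:00 to midnight daily, and one commuter dwelling symmetrically at two
anchors 3 km apart (11 h 45 min each, 15-min transitions). Streams: screen
sessions (3/day, 10 min, fixed daytime clock times), calls (Poisson 5/day,
exponential durations), a 5 %/h battery sawtooth, day/night lognormal
light, 2-min GPS with ~1 m jitter, per-minute heart rate (70 bpm baseline,
10 bpm circadian sinusoid), two 30-min walking bouts/day, and a tonic EDA
level. Identical profile + seed gives byte-identical files; all planted
quantities are recorded in `ground_truth.json`.

What a green end-to-end test establishes: the pipeline recovers planted
episode counts exactly, yield ratios to ±0.01, the anchor count, and the
symmetric-dwell radius of gyration to ±5%. What it does not establish:
robustness to real-world phenomena the generator does not model — GPS
multipath and urban-canyon noise, irregular human schedules, sensor clock
drift, vendor-specific log quirks, or adversarial missingness correlated
with behavior.

## 10. Known limitations

* iOS screen semantics (no off event) are a convention, not a platform
  specification.
* Clock times derived inside multi-day sleep segments use segment start
  plus elapsed time; a DST transition inside one sleep bout shifts
  bed/wake clock features by the offset change.
* The wall-time definition of frequency windows means their *elapsed*
  length varies on DST days (by design; see §2).
* Cosine routine indices are undefined on sub-2-day segments.
* The DBSCAN implementation is O(n²) in stationary points; at the default
  2-min GPS sampling this is comfortable for month-scale studies but a
  spatial index would be needed for year-scale high-rate traces.
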
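# Default QA run configuration. Thresholds mirror modelConfig() /
# contiguityConfig() defaults; the femoral thresholds are calibration
# constants fitted once on the synthetic phantom cohorts.
manifest: manifest.csv
checks:
- extent
- region_growing
- slice_extent
model:
  bladderVolumePercentile: 25.0
  bladderRatioLowPercentile: 10.0
  bladderRatioHighPercentile: 90.0
  femoralVolumePercentile: 20.0
  femoralIsRangeMmThreshold: 100.0
  femoralLrOverApRatioThreshold: 1.15
  sliceExtentPercentile: 90.0
  sliceExtentCombine: and
  minCohortRows: 8
contiguity:
  neighborRadius: 1.7320508075688772
  seedRule: lowest_linear_index
out_json: report.json
stable_output: yes
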
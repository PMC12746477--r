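criteria:
- structure: CTV4000
  metric: V40Gy
  comparator: '>'
  limit: 95.0
  tolerance: -5.0
  unit: '%'
- structure: PTV
  metric: V36.25Gy
  comparator: '>'
  limit: 95.0
  tolerance: -5.0
  unit: '%'
- structure: PTV
  metric: V34.40Gy
  comparator: '>'
  limit: 98.0
  tolerance: -5.0
  unit: '%'
- structure: Rectum
  metric: Dmax
  comparator: <
  limit: 40.0
  tolerance: 0.0
  unit: Gy
- structure: Rectum
  metric: V38Gy
  comparator: <
  limit: 0.1
  tolerance: 0.0
  unit: cc
- structure: Rectum
  metric: V36Gy
  comparator: <
  limit: 1.0
  tolerance: 1.0
  unit: cc
- structure: Rectum
  metric: V29Gy
  comparator: <
  limit: 20.0
  tolerance: 1.0
  unit: '%'
- structure: Bladder
  metric: V37Gy
  comparator: <
  limit: 10.0
  tolerance: 0.5
  unit: cc
- structure: Bladder
  metric: V18.1Gy
  comparator: <
  limit: 50.0
  tolerance: 2.5
  unit: '%'
- structure: Femur R
  metric: V14.5Gy
  comparator: <
  limit: 5.0
  tolerance: 0.5
  unit: '%'
- structure: Femur L
  metric: V14.5Gy
  comparator: <
  limit: 5.0
  tolerance: 0.5
  unit: '%'
- structure: Urethra
  metric: D50%
  comparator: <
  limit: 41.0
  tolerance: 1.5
  unit: Gy
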
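horizon: 720.0
drinks:
- start: 0.0
  duration: 10.0
  volume: 0.226235741444867
  EtOHConc: 0.05
  kcalLiquidPerVol: 440.0
  volDrinkPerTime: 0.022623574144487
- start: 15.0
  duration: 10.0
  volume: 0.226235741444867
  EtOHConc: 0.05
  kcalLiquidPerVol: 440.0
  volDrinkPerTime: 0.022623574144487
- start: 30.0
  duration: 10.0
  volume: 0.226235741444867
  EtOHConc: 0.05
  kcalLiquidPerVol: 440.0
  volDrinkPerTime: 0.022623574144487
- start: 45.0
  duration: 10.0
  volume: 0.226235741444867
  EtOHConc: 0.05
  kcalLiquidPerVol: 440.0
  volDrinkPerTime: 0.022623574144487
- start: 120.0
  duration: 30.0
  volume: 0.226235741444867
  EtOHConc: 0.2
  kcalLiquidPerVol: 0.0
  volDrinkPerTime: 0.007541191381496
meals:
- start: 0.0
  MealKcal: 300.0
  duration: 1.0
- start: 180.0
  MealKcal: 500.0
  duration: 1.0
urinate:
- 30.0
- 60.0
- 90.0
- 120.0
- 150.0
- 180.0
- 210.0
- 240.0
- 270.0
- 300.0
- 330.0
- 360.0
- 390.0
- 420.0
- 450.0
- 480.0
- 510.0
- 540.0
- 570.0
- 600.0
- 630.0
- 660.0
- 690.0
- 720.0
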
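n_samples: 360
n_taxa: 150
modifier_prevalence: 0.189
zero_inflation:
- 0.05
- 0.056174496644295
- 0.062348993288591
- 0.068523489932886
- 0.074697986577181
- 0.080872483221477
- 0.087046979865772
- 0.093221476510067
- 0.099395973154362
- 0.105570469798658
- 0.111744966442953
- 0.117919463087248
- 0.124093959731544
- 0.130268456375839
- 0.136442953020134
- 0.14261744966443
- 0.148791946308725
- 0.15496644295302
- 0.161140939597315
- 0.167315436241611
- 0.173489932885906
- 0.179664429530201
- 0.185838926174497
- 0.192013422818792
- 0.198187919463087
- 0.204362416107383
- 0.210536912751678
- 0.216711409395973
- 0.222885906040268
- 0.229060402684564
- 0.235234899328859
- 0.241409395973154
- 0.24758389261745
- 0.253758389261745
- 0.25993288590604
- 0.266107382550336
- 0.272281879194631
- 0.278456375838926
- 0.284630872483221
- 0.290805369127517
- 0.296979865771812
- 0.303154362416107
- 0.309328859060403
- 0.315503355704698
- 0.321677852348993
- 0.327852348993289
- 0.334026845637584
- 0.340201342281879
- 0.346375838926174
- 0.35255033557047
- 0.358724832214765
- 0.36489932885906
- 0.371073825503356
- 0.377248322147651
- 0.383422818791946
- 0.389597315436242
- 0.395771812080537
- 0.401946308724832
- 0.408120805369127
- 0.414295302013423
- 0.420469798657718
- 0.426644295302013
- 0.432818791946309
- 0.438993288590604
- 0.445167785234899
- 0.451342281879195
- 0.45751677852349
- 0.463691275167785
- 0.469865771812081
- 0.476040268456376
- 0.482214765100671
- 0.488389261744966
- 0.494563758389262
- 0.500738255033557
- 0.506912751677852
- 0.513087248322148
- 0.519261744966443
- 0.525436241610738
- 0.531610738255034
- 0.537785234899329
- 0.543959731543624
- 0.550134228187919
- 0.556308724832215
- 0.56248322147651
- 0.568657718120805
- 0.574832214765101
- 0.581006711409396
- 0.587181208053691
- 0.593355704697987
- 0.599530201342282
- 0.605704697986577
- 0.611879194630872
- 0.618053691275168
- 0.624228187919463
- 0.630402684563758
- 0.636577181208054
- 0.642751677852349
- 0.648926174496644
- 0.65510067114094
- 0.661275167785235
- 0.66744966442953
- 0.673624161073826
- 0.679798657718121
- 0.685973154362416
- 0.692147651006711
- 0.698322147651007
- 0.704496644295302
- 0.710671140939597
- 0.716845637583893
- 0.723020134228188
- 0.729194630872483
- 0.735369127516779
- 0.741543624161074
- 0.747718120805369
- 0.753892617449664
- 0.76006711409396
- 0.766241610738255
- 0.77241610738255
- 0.778590604026846
- 0.784765100671141
- 0.790939597315436
- 0.797114093959732
- 0.803288590604027
- 0.809463087248322
- 0.815637583892617
- 0.821812080536913
- 0.827986577181208
- 0.834161073825503
- 0.840335570469799
- 0.846510067114094
- 0.852684563758389
- 0.858859060402685
- 0.86503355704698
- 0.871208053691275
- 0.87738255033557
- 0.883557046979866
- 0.889731543624161
- 0.895906040268456
- 0.902080536912752
- 0.908255033557047
- 0.914429530201342
- 0.920604026845638
- 0.926778523489933
- 0.932953020134228
- 0.939127516778523
- 0.945302013422819
- 0.951476510067114
- 0.957651006711409
- 0.963825503355705
- 0.97
concentration:
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
- 0.5
cliques:
- members:
  - 70.0
  - 75.0
  joint_prevalence: 0.25
  effect:
    secure: 0.05
    insecure: 0.29
covariate_effects:
  age: 0.003
  fiber: -0.002
  smoker: 0.04
  modifier: 0.06
intercept: 0.4
noise_sd: 0.15
missing_rate: 0.015
seed: 1
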
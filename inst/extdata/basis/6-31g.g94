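! 6-31G split-valence basis (standard published parameters)
! Elements: H O
****
H 0
S 3 1.00
     18.73113700           0.03349460
      2.82539370           0.23472695
      0.64012170           0.81375733
S 1 1.00
      0.16127780           1.00000000
****
O 0
S 6 1.00
   5484.67170000           0.00183110
    825.23495000           0.01395010
    188.04696000           0.06844510
     52.96450000           0.23271430
     16.89757000           0.47019300
      5.79963530           0.35852090
SP 3 1.00
     15.53961600          -0.11077750           0.07087430
      3.59993360          -0.14802630           0.33975280
      1.01376180           1.13076700           0.72715860
SP 1 1.00
      0.27000580           1.00000000           1.00000000
****
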
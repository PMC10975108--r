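sex,age_months,M,L,S
female,36,15.6042,-1.696,0.082
female,37,15.58125,-1.692,0.0822
female,38,15.5592,-1.688,0.0824
female,39,15.53805,-1.684,0.0826
female,40,15.5178,-1.68,0.0828
female,41,15.49845,-1.676,0.083
female,42,15.48,-1.672,0.0832
female,43,15.46245,-1.668,0.0834
female,44,15.4458,-1.664,0.0836
female,45,15.43005,-1.66,0.0838
female,46,15.4152,-1.656,0.084
female,47,15.40125,-1.652,0.0842
female,48,15.3882,-1.648,0.0844
female,49,15.37605,-1.644,0.0846
female,50,15.3648,-1.64,0.0848
female,51,15.35445,-1.636,0.085
female,52,15.345,-1.632,0.0852
female,53,15.33645,-1.628,0.0854
female,54,15.3288,-1.624,0.0856
female,55,15.32205,-1.62,0.0858
female,56,15.3162,-1.616,0.086
female,57,15.31125,-1.612,0.0862
female,58,15.3072,-1.608,0.0864
female,59,15.30405,-1.604,0.0866
female,60,15.3018,-1.6,0.0868
female,61,15.30045,-1.596,0.087
female,62,15.3,-1.592,0.0872
female,63,15.30045,-1.588,0.0874
female,64,15.3018,-1.584,0.0876
female,65,15.30405,-1.58,0.0878
female,66,15.3072,-1.576,0.088
female,67,15.31125,-1.572,0.0882
female,68,15.3162,-1.568,0.0884
female,69,15.32205,-1.564,0.0886
female,70,15.3288,-1.56,0.0888
female,71,15.33645,-1.556,0.089
female,72,15.345,-1.552,0.0892
female,73,15.35445,-1.548,0.0894
female,74,15.3648,-1.544,0.0896
female,75,15.37605,-1.54,0.0898
female,76,15.3882,-1.536,0.09
female,77,15.40125,-1.532,0.0902
female,78,15.4152,-1.528,0.0904
female,79,15.43005,-1.524,0.0906
female,80,15.4458,-1.52,0.0908
female,81,15.46245,-1.516,0.091
female,82,15.48,-1.512,0.0912
female,83,15.49845,-1.508,0.0914
female,84,15.5178,-1.504,0.0916
male,36,15.7542,-1.646,0.084
male,37,15.73125,-1.642,0.0842
male,38,15.7092,-1.638,0.0844
male,39,15.68805,-1.634,0.0846
male,40,15.6678,-1.63,0.0848
male,41,15.64845,-1.626,0.085
male,42,15.63,-1.622,0.0852
male,43,15.61245,-1.618,0.0854
male,44,15.5958,-1.614,0.0856
male,45,15.58005,-1.61,0.0858
male,46,15.5652,-1.606,0.086
male,47,15.55125,-1.602,0.0862
male,48,15.5382,-1.598,0.0864
male,49,15.52605,-1.594,0.0866
male,50,15.5148,-1.59,0.0868
male,51,15.50445,-1.586,0.087
male,52,15.495,-1.582,0.0872
male,53,15.48645,-1.578,0.0874
male,54,15.4788,-1.574,0.0876
male,55,15.47205,-1.57,0.0878
male,56,15.4662,-1.566,0.088
male,57,15.46125,-1.562,0.0882
male,58,15.4572,-1.558,0.0884
male,59,15.45405,-1.554,0.0886
male,60,15.4518,-1.55,0.0888
male,61,15.45045,-1.546,0.089
male,62,15.45,-1.542,0.0892
male,63,15.45045,-1.538,0.0894
male,64,15.4518,-1.534,0.0896
male,65,15.45405,-1.53,0.0898
male,66,15.4572,-1.526,0.09
male,67,15.46125,-1.522,0.0902
male,68,15.4662,-1.518,0.0904
male,69,15.47205,-1.514,0.0906
male,70,15.4788,-1.51,0.0908
male,71,15.48645,-1.506,0.091
male,72,15.495,-1.502,0.0912
male,73,15.50445,-1.498,0.0914
male,74,15.5148,-1.494,0.0916
male,75,15.52605,-1.49,0.0918
male,76,15.5382,-1.486,0.092
male,77,15.55125,-1.482,0.0922
male,78,15.5652,-1.478,0.0924
male,79,15.58005,-1.474,0.0926
male,80,15.5958,-1.47,0.0928
male,81,15.61245,-1.466,0.093
male,82,15.63,-1.462,0.0932
male,83,15.64845,-1.458,0.0934
male,84,15.6678,-1.454,0.0936
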
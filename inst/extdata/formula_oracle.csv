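formula,mw,amw,h_percent
C8H9NO2,151.165000,7.5582500000,45.0000000000
C9H8O4,180.159000,8.5790000000,38.0952380952
C13H18O2,206.285000,6.2510606061,54.5454545455
C8H10N4O2,194.194000,8.0914166667,41.6666666667
CH4,16.043000,3.2086000000,80.0000000000
H2O,18.015000,6.0050000000,66.6666666667
C6H6,78.114000,6.5095000000,50.0000000000
C6H12O6,180.156000,7.5065000000,50.0000000000
C33H35FN2O5,558.650000,7.3506578947,46.0526315789
C16H19N3O5S,365.404000,8.3046363636,43.1818181818
C18H26ClN3,319.877000,6.6641041667,54.1666666667
C2HBrClF3,197.378000,24.6722500000,12.5000000000
C4H11N5,129.167000,6.4583500000,55.0000000000
C25H38O5,418.574000,6.1555000000,55.8823529412
C17H18FN3O3,331.347000,7.8892142857,42.8571428571
C16H13ClN2O,284.743000,8.6285757576,39.3939393939
C4H3FN2O2,130.078000,10.8398333333,25.0000000000
C25H29I2NO3,645.311000,10.7551833333,48.3333333333
C7H5N3O6,227.132000,10.8158095238,23.8095238095
C16H18N2O4S,334.390000,8.1558536585,43.9024390244
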
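ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
0.308251 0.487091 0.588839 0.431805 0.445682 0.381245 0.387717 0.341431 0.211464 0.172252 0.26237 0.0337635       0 0.14394 0.249019 0.338451
0.409957 0.512073 0.607024 0.363372 0.359539 0.294666 0.263151 0.188697 0.00772644       0 0.0868745       0       0       0 0.0543137 0.158234
0.436036 0.417467 0.393812 0.290243 0.329629 0.188658 0.168355 0.131424 0.116241 0.15857 0.161173       0       0 0.00937458 0.0797243 0.157826
0.312022 0.344323 0.284755 0.210144 0.165119 0.115921 0.0305913 0.102182 0.120584 0.162143 0.11692 0.0621978 0.0305271 0.171197 0.148273 0.171517
0.294059 0.283284 0.339006 0.343837 0.285163 0.190945 0.0905078 0.109463 0.207576 0.239866 0.218455 0.166533 0.260385 0.381199 0.328222 0.348688
0.427913 0.234259 0.235626 0.330999 0.230081 0.0349492       0 0.0127876 0.225033 0.192935 0.0571075 0.0242811 0.183681  0.2782 0.121934 0.0888105
0.43518 0.240918 0.329618 0.416763 0.239589 0.0748028 0.0437484 0.0497005 0.235764 0.151167 0.0201398 0.0309245 0.263007 0.314147 0.142777 0.0496248
0.350915 0.204725 0.329137 0.392255 0.194466       0       0 0.0181858 0.20025       0       0       0 0.197355 0.278361 0.128944 0.0626038
0.286333 0.111098 0.175473 0.306538 0.193717       0       0 0.160958 0.336205 0.195745 0.0648577 0.0592616 0.37258 0.455852 0.259044 0.17834
0.338047 0.126187 0.187558 0.238977 0.0985356 0.0313895 0.050432 0.253718 0.317083 0.166641 0.0359094 0.0575496 0.254712 0.34584 0.0855728 0.0636145
0.40531 0.195326 0.389841 0.384593 0.277654 0.228518 0.208023 0.332586 0.283559 0.128111 0.0434569       0 0.0907379 0.0839286       0       0
0.394518 0.180947 0.208296 0.139105 0.0581079 0.0114555 0.0135523 0.112032 0.100198       0       0       0       0       0       0       0
0.202189 0.0843156 0.0933623 0.0229714 0.013049 0.0905536 0.0375326 0.132475 0.0981292 0.0192999 0.032246       0       0       0 0.00492122 0.0534226
0.0684697       0       0       0       0 0.155209 0.0941388 0.117777 0.107879 0.0760137 0.0883667 0.0323441 0.0209893 0.00942732 0.139479 0.259431
0.133094       0       0       0       0 0.172235 0.0411943 0.144665 0.125787 0.180265 0.151613 0.0800815 0.00964772 0.0331236 0.0876215 0.178153
0.151358 0.0853245 0.00326168 0.00581425       0 0.266199 0.0887421 0.174317 0.180515 0.113771 0.115212 0.0957747       0 0.0137642 0.0825693 0.11289
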
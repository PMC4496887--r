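<?xml version="1.0" encoding="UTF-8"?>
<simulationSetup mode="ssa" seed="1" replicates="1" fraction="1">
  <end time="172800"/>
  <context volume="1e-09" avogadro="6e+23"/>
  <leap criticalThreshold="20" epsilon="0.03"/>
  <places>
    <place id="IR" concentration="9e-13"/>
    <place id="IR_I" concentration="0"/>
    <place id="IR_I_P" concentration="0"/>
    <place id="IR_I_P_Int" concentration="0"/>
    <place id="IR_Int" concentration="1e-13"/>
    <place id="Insulin" constant="true">
      <expression>Time % 86400 &gt;= 32400 , Time % 86400 &lt; 43200 : 36000 + 180000 * exp(-(Time % 86400 - 32400) / 2345.19020227756) ; Time % 86400 &gt;= 46800 , Time % 86400 &lt; 57600 : 36000 + 180000 * exp(-(Time % 86400 - 46800) / 2345.19020227756) ; Time % 86400 &gt;= 64800 , Time % 86400 &lt; 75600 : 36000 + 180000 * exp(-(Time % 86400 - 64800) / 2345.19020227756) ; 36000</expression>
    </place>
  </places>
  <rates>
    <rate transition="Bind_Insulin" kind="mass_action" value="1000000"/>
    <rate transition="Diss_Insulin" kind="mass_action" value="0.00333"/>
    <rate transition="Inter_IR" kind="mass_action" value="5.56e-06"/>
    <rate transition="Phos_IR_I" kind="mass_action" value="41.66"/>
    <rate transition="Dephos_IR_I_P" kind="mass_action" value="0.00333"/>
    <rate transition="Inter_IR_I_P" kind="mass_action" value="3.5e-05"/>
    <rate transition="Deinter_IR_I_P" kind="mass_action" value="3.5e-06"/>
    <rate transition="Dephos_IR_I_P_Int" kind="mass_action" value="0.00768"/>
    <rate transition="Deinter_IR" kind="mass_action" value="5e-05"/>
    <rate transition="Degradation" kind="mass_action" value="2.783e-06"/>
    <rate transition="Synthesis" kind="conditional" units="mass_action">
      <text>IR_Int + IR_I_P_Int &gt;= 60 : 2.78e-19 ; IR_Int + IR_I_P_Int &lt; 60 : 1.67e-18</text>
    </rate>
  </rates>
</simulationSetup>
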